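# Halton-based quasi-random standard-normal draws with optional antithetic
# mirroring. One prime base per mixing dimension; each individual owns a
# contiguous, internally symmetric block of draws.

.is_prime <- function(p) {
  if (length(p) != 1L || is.na(p) || p != floor(p) || p < 2) return(FALSE)
  if (p < 4) return(TRUE)
  if (p %% 2 == 0) return(FALSE)
  d <- 3
  while (d * d <= p) {
    if (p %% d == 0) return(FALSE)
    d <- d + 2
  }
  TRUE
}

.first_primes <- function(n) {
  out <- integer(0)
  cand <- 2L
  while (length(out) < n) {
    if (.is_prime(cand)) out <- c(out, cand)
    cand <- cand + 1L
  }
  out
}

#' Draw configuration for quasi-random mixing draws
#'
#' Describes how standard-normal quasi-random draws are generated for a panel
#' mixed logit: one prime base per mixing dimension (named after the mixed
#' parameter it serves), the number of draws per individual `R`, and the
#' antithetic mode.
#'
#' Under `antithetic = "full"` each Halton base point is paired with all
#' `2^n - 1` coordinate mirrors, so `R` must be a multiple of `2^n`; under
#' `"one_dim"` each point is paired with its single global complement, so `R`
#' must be even.
#'
#' @param primes Named integer vector of distinct primes, one per mixing
#'   dimension; names are the mixed-parameter labels. Defaults to the first
#'   `n_dims` primes named `dim1`, `dim2`, ...
#' @param draws_per_individual Number of draws `R` per individual.
#' @param n_individuals Number of individuals `I`.
#' @param antithetic One of `"none"`, `"one_dim"`, `"full"`.
#' @param drop Number of initial Halton elements discarded from each
#'   sequence before use (default 10, removing the correlated initial run).
#' @param n_dims Number of mixing dimensions; inferred from `primes` when
#'   those are given.
#' @param seed Integer, retained for configurations that enable explicit
#'   randomization; the deterministic Halton constructions here ignore it.
#' @return An object of class `draw_config`.
#' @examples
#' draw_config(primes = c(B = 2, C = 3, D = 5),
#'             draws_per_individual = 96, n_individuals = 10,
#'             antithetic = "full")
#' @export
draw_config <- function(primes = NULL, draws_per_individual, n_individuals,
                        antithetic = c("none", "one_dim", "full"),
                        drop = 10L, n_dims = NULL, seed = NA_integer_) {
  antithetic <- match.arg(antithetic)
  if (is.null(primes)) {
    if (is.null(n_dims)) stop("give either `primes` or `n_dims`")
    primes <- .first_primes(n_dims)
    names(primes) <- paste0("dim", seq_len(n_dims))
  }
  if (is.null(names(primes)) || anyNA(names(primes)) || any(names(primes) == ""))
    names(primes) <- paste0("dim", seq_along(primes))
  primes <- vapply(primes, as.integer, integer(1))
  n <- length(primes)
  if (!is.null(n_dims) && n_dims != n)
    stop("`n_dims` disagrees with length(primes)")
  bad <- !vapply(primes, .is_prime, logical(1))
  if (any(bad))
    stop("invalid Halton base(s): ", paste(primes[bad], collapse = ", "),
         " (each base must be prime and >= 2)")
  if (anyDuplicated(primes))
    stop("prime bases must be pairwise distinct")
  R <- as.integer(draws_per_individual)
  I <- as.integer(n_individuals)
  drop <- as.integer(drop)
  if (R < 1L || I < 1L || drop < 0L) stop("R, I must be >= 1 and drop >= 0")
  .check_R_mode(R, n, antithetic)
  structure(list(primes = primes, n_dims = n,
                 draws_per_individual = R, n_individuals = I,
                 drop = drop, antithetic_mode = antithetic, seed = seed),
            class = "draw_config")
}

.check_R_mode <- function(R, n, mode) {
  if (mode == "full") {
    block <- 2L^n
    if (R %% block != 0L) {
      lo <- block * (R %/% block)
      hi <- lo + block
      stop("with fully antithetic draws in ", n, " dimensions, R must be a ",
           "multiple of 2^", n, " = ", block, "; R = ", R,
           " is invalid (nearest valid values: ", lo, " and ", hi, ")")
    }
  } else if (mode == "one_dim") {
    if (R %% 2L != 0L)
      stop("one-dimensionally antithetic draws require an even R; R = ", R)
  }
  invisible(TRUE)
}

#' Round a draw count up to the nearest valid multiple for a mode
#'
#' Convenience used by the command-line interface: the adjustment is explicit
#' and reported, never silent.
#'
#' @param R Requested draws per individual.
#' @param n_dims Number of mixing dimensions.
#' @param antithetic Antithetic mode.
#' @param quiet Suppress the message describing the adjustment.
#' @return The adjusted (possibly unchanged) draw count.
#' @export
round_draws_up <- function(R, n_dims, antithetic, quiet = FALSE) {
  block <- switch(antithetic, full = 2L^n_dims, one_dim = 2L, none = 1L)
  R2 <- as.integer(ceiling(R / block) * block)
  if (R2 != R && !quiet)
    message("adjusted draws per individual from ", R, " to ", R2,
            " (multiple of ", block, " required for mode '", antithetic, "')")
  R2
}

#' Radical inverse of an integer in a prime base
#'
#' Reverses the base-`base` digits of `index` about the radix point, giving a
#' value in (0, 1). This is the elementary building block of the Halton
#' sequence.
#'
#' @param index Positive integer (vectorized).
#' @param base A prime base, >= 2.
#' @return Numeric vector of values in (0, 1).
#' @examples
#' radical_inverse(1, 2)  # 0.5
#' radical_inverse(3, 2)  # 0.75
#' @export
radical_inverse <- function(index, base) {
  if (!.is_prime(base))
    stop("invalid Halton base: ", base, " (must be a prime >= 2)")
  index <- as.numeric(index)
  if (any(index < 1 | index != floor(index)))
    stop("index must be a positive integer")
  out <- numeric(length(index))
  f <- 1 / base
  i <- index
  while (any(i > 0)) {
    out <- out + (i %% base) * f
    i <- i %/% base
    f <- f / base
  }
  out
}

#' Halton sequence in a prime base
#'
#' Returns `count` consecutive elements of the Halton sequence in `base`,
#' starting after `drop` discarded initial elements.
#'
#' @param base Prime base.
#' @param count Number of elements to return.
#' @param drop Number of initial elements to discard.
#' @return Numeric vector of length `count`, all values in (0, 1).
#' @examples
#' halton_sequence(2, 5)  # 0.5 0.25 0.75 0.125 0.625
#' @export
halton_sequence <- function(base, count, drop = 0L) {
  count <- as.integer(count)
  drop <- as.integer(drop)
  if (count < 1L) stop("count must be >= 1")
  if (drop < 0L) stop("drop must be >= 0")
  radical_inverse(seq.int(drop + 1L, drop + count), base)
}

#' Map a unit-interval value to a standard-normal draw
#'
#' The standard-normal quantile transform. Antisymmetric about 0.5:
#' `unit_to_normal(1 - u) == -unit_to_normal(u)`.
#'
#' @param u Values strictly inside (0, 1).
#' @return Standard-normal values.
#' @export
unit_to_normal <- function(u) {
  if (any(u <= 0 | u >= 1))
    stop("u must lie strictly inside (0, 1); the quantile is infinite at 0/1")
  stats::qnorm(u)
}

#' Expand unit points into all coordinate mirrors (fully antithetic)
#'
#' Each base point `d` in n dimensions is expanded into the `2^n` points
#' obtained by replacing any subset of coordinates `d_k` with `1 - d_k`.
#' Output ordering per base point is binary-mask order: mask bit `k` set means
#' dimension `k` is flipped, the base point itself is mask 0.
#'
#' @param base_points M x n matrix of values in (0, 1).
#' @return (M * 2^n) x n matrix, blocks of `2^n` rows per base point.
#' @export
make_full_antithetic <- function(base_points) {
  base_points <- rbind(base_points)
  if (any(base_points <= 0 | base_points >= 1))
    stop("base points must lie strictly inside (0, 1)")
  M <- nrow(base_points); n <- ncol(base_points)
  K <- 2L^n
  out <- matrix(NA_real_, M * K, n)
  for (mask in 0:(K - 1L)) {
    pts <- base_points
    for (k in seq_len(n)) {
      if (bitwAnd(mask, bitwShiftL(1L, k - 1L)) != 0L)
        pts[, k] <- 1 - pts[, k]
    }
    out[(seq_len(M) - 1L) * K + mask + 1L, ] <- pts
  }
  out
}

#' Pair each unit point with its single global complement
#'
#' One-dimensionally antithetic mirroring: each base point `d` is paired only
#' with `(1 - d_1, ..., 1 - d_n)`. For `n >= 2` this leaves `2^n - 2` of the
#' sign quadrants unmatched in normal space.
#'
#' @param base_points M x n matrix of values in (0, 1).
#' @return (2M) x n matrix, each base point immediately followed by its
#'   complement.
#' @export
make_one_dim_antithetic <- function(base_points) {
  base_points <- rbind(base_points)
  if (any(base_points <= 0 | base_points >= 1))
    stop("base points must lie strictly inside (0, 1)")
  M <- nrow(base_points); n <- ncol(base_points)
  out <- matrix(NA_real_, 2L * M, n)
  out[seq(1L, 2L * M, by = 2L), ] <- base_points
  out[seq(2L, 2L * M, by = 2L), ] <- 1 - base_points
  out
}

.unit_points_matrix <- function(config) {
  n <- config$n_dims
  R <- config$draws_per_individual
  I <- config$n_individuals
  mode <- config$antithetic_mode
  block <- switch(mode, none = 1L, one_dim = 2L, full = 2L^n)
  Rb <- R %/% block
  base <- matrix(NA_real_, I * Rb, n)
  for (k in seq_len(n))
    base[, k] <- halton_sequence(config$primes[[k]], I * Rb, config$drop)
  switch(mode,
         none = base,
         one_dim = make_one_dim_antithetic(base),
         full = make_full_antithetic(base))
}

#' Generate unit-interval quasi-random points for a configuration
#'
#' Builds the Halton points (one prime per dimension, after dropping the
#' initial `drop` elements) and applies the configured antithetic expansion.
#' Each individual receives a contiguous block of `R` points whose antithetic
#' mirror sets are wholly contained within that individual, as required for
#' per-individual symmetry of the panel likelihood.
#'
#' @param config A [draw_config()].
#' @return An object of class `unit_draw_set`: list with `points`
#'   (I x R x n array, values in (0, 1)) and `config`.
#' @export
build_unit_draws <- function(config) {
  stopifnot(inherits(config, "draw_config"))
  .check_R_mode(config$draws_per_individual, config$n_dims,
                config$antithetic_mode)
  u <- .unit_points_matrix(config)
  I <- config$n_individuals
  R <- config$draws_per_individual
  n <- config$n_dims
  pts <- array(NA_real_, dim = c(I, R, n),
               dimnames = list(NULL, NULL, names(config$primes)))
  for (k in seq_len(n))
    pts[, , k] <- t(matrix(u[, k], nrow = R, ncol = I))
  structure(list(points = pts, config = config), class = "unit_draw_set")
}

#' Generate standard-normal quasi-random draws
#'
#' Maps [build_unit_draws()] through the standard-normal quantile. Under the
#' fully antithetic mode every individual's draw set is exactly symmetric
#' under all `2^n` coordinate sign-flip patterns, so per-dimension sums and
#' skewness vanish (to floating-point accuracy).
#'
#' @param config A [draw_config()].
#' @return An object of class `normal_draw_set`: list with `points`
#'   (I x R x n array of standard-normal values) and `config`.
#' @examples
#' cfg <- draw_config(primes = c(B = 2, C = 3), draws_per_individual = 8,
#'                    n_individuals = 2, antithetic = "full")
#' d <- build_draws(cfg)
#' range(apply(d$points, c(1, 3), sum))  # ~0: mirror cancellation
#' @export
build_draws <- function(config) {
  u <- build_unit_draws(config)
  structure(list(points = stats::qnorm(u$points), config = config),
            class = "normal_draw_set")
}

#' Skewness coefficient of one dimension of a draw set
#'
#' Standardized third central moment of the pooled values in dimension `dim`.
#' Fully antithetic draw sets have skewness exactly zero by symmetry.
#'
#' @param draws A `normal_draw_set`.
#' @param dim Dimension index or mixed-parameter name.
#' @return The skewness coefficient.
#' @export
skewness_coefficient <- function(draws, dim) {
  stopifnot(inherits(draws, "normal_draw_set"))
  x <- as.vector(draws$points[, , dim])
  if (length(x) < 3L) stop("need at least 3 draws")
  xc <- x - mean(x)
  m2 <- mean(xc^2)
  if (m2 == 0) stop("skewness undefined: zero variance")
  mean(xc^3) / m2^1.5
}

#' @export
print.draw_config <- function(x, ...) {
  cat("Draw configuration:", x$n_dims, "mixing dimension(s)\n")
  cat("  primes:", paste(sprintf("%s=%d", names(x$primes), x$primes),
                         collapse = ", "), "\n")
  cat("  draws/individual:", x$draws_per_individual,
      " individuals:", x$n_individuals,
      " drop:", x$drop, "\n")
  cat("  antithetic mode:", x$antithetic_mode, "\n")
  invisible(x)
}

#' @export
print.normal_draw_set <- function(x, ...) {
  d <- dim(x$points)
  cat("Standard-normal quasi-random draw set:",
      d[1], "individuals x", d[2], "draws x", d[3], "dimension(s),",
      "mode", x$config$antithetic_mode, "\n")
  invisible(x)
}

#' Export a draw set to CSV
#'
#' Long layout: one row per (individual, draw), one column per dimension, for
#' cross-implementation comparison.
#'
#' @param draws A `normal_draw_set` or `unit_draw_set`.
#' @param path File to write.
#' @return `path`, invisibly.
#' @export
write_draws_csv <- function(draws, path) {
  d <- dim(draws$points)
  df <- data.frame(individual = rep(seq_len(d[1]), each = d[2]),
                   draw_index = rep(seq_len(d[2]), times = d[1]))
  for (k in seq_len(d[3]))
    df[[paste0("dim_", dimnames(draws$points)[[3]][k])]] <-
      as.vector(t(draws$points[, , k]))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a draw set written by [write_draws_csv()]
#'
#' @param path CSV file.
#' @param config Optional `draw_config` to attach.
#' @return A `normal_draw_set` (config may be `NULL` if not supplied).
#' @export
read_draws_csv <- function(path, config = NULL) {
  df <- utils::read.csv(path)
  dims <- grep("^dim_", names(df), value = TRUE)
  I <- max(df$individual)
  R <- max(df$draw_index)
  pts <- array(NA_real_, c(I, R, length(dims)),
               dimnames = list(NULL, NULL, sub("^dim_", "", dims)))
  ord <- order(df$individual, df$draw_index)
  for (k in seq_along(dims))
    pts[, , k] <- t(matrix(df[[dims[k]]][ord], nrow = R, ncol = I))
  structure(list(points = pts, config = config), class = "normal_draw_set")
}
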