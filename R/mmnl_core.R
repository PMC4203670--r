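# Panel mixed multinomial logit: conventional logit kernel, Choleski-
# parameterized normal mixing, simulated log-likelihood, and evaluation of
# the likelihood across all 2^n sign-flip quadrants of the Choleski factor.

#' Panel discrete-choice data container
#'
#' Long-format panel choice data: one row per (individual, situation,
#' alternative), exactly one chosen alternative per situation, and a common
#' alternative universe across situations. Alternative-specific constants for
#' the non-base alternatives form the (possibly mixed) coefficients; any extra
#' numeric columns are treated as alternative attributes with fixed
#' coefficients.
#'
#' @param data Data frame with columns `individual`, `situation`,
#'   `alternative`, `chosen` (0/1), plus optional numeric attribute columns.
#' @param base_alternative Label of the alternative whose systematic utility
#'   is fixed at zero. Defaults to the first alternative label.
#' @return An object of class `choice_panel`.
#' @export
choice_panel <- function(data, base_alternative = NULL) {
  need <- c("individual", "situation", "alternative", "chosen")
  if (!all(need %in% names(data)))
    stop("data must have columns ", paste(need, collapse = ", "))
  alts <- sort(unique(as.character(data$alternative)))
  if (is.null(base_alternative)) base_alternative <- alts[1]
  base_alternative <- as.character(base_alternative)
  if (!base_alternative %in% alts)
    stop("base alternative '", base_alternative, "' not found")
  attr_cols <- setdiff(names(data), need)
  J <- length(alts)
  data <- data[order(data$individual, data$situation,
                     match(as.character(data$alternative), alts)), ,
               drop = FALSE]
  rownames(data) <- NULL
  sit_key <- paste(data$individual, data$situation, sep = "\r")
  if (any(table(sit_key) != J) ||
      !all(tapply(as.character(data$alternative), sit_key,
                  function(a) identical(sort(a), alts))))
    stop("every situation must contain each alternative exactly once")
  if (!all(tapply(data$chosen, sit_key, sum) == 1))
    stop("every situation must have exactly one chosen alternative")
  structure(list(data = data, alternatives = alts,
                 base_alternative = base_alternative,
                 attr_cols = attr_cols,
                 individuals = unique(data$individual),
                 n_individuals = length(unique(data$individual)),
                 n_alternatives = J,
                 cache = new.env(parent = emptyenv())),
            class = "choice_panel")
}

#' @export
print.choice_panel <- function(x, ...) {
  cat("Choice panel:", x$n_individuals, "individuals,",
      nrow(x$data) / x$n_alternatives, "choice situations,",
      x$n_alternatives, "alternatives (base:", x$base_alternative, ")\n")
  if (length(x$attr_cols))
    cat("  attributes:", paste(x$attr_cols, collapse = ", "), "\n")
  invisible(x)
}

#' Parameters of the normal mixing distribution
#'
#' Means and lower-triangular Choleski factor of the mixing distribution of
#' the random coefficients, plus values of any non-mixed coefficients. The
#' ordering of `means`/`chol` rows must match the prime-to-dimension
#' assignment of the accompanying [draw_config()].
#'
#' @param means Named numeric vector of mixing means (names = mixed-parameter
#'   labels, i.e. non-base alternative labels for mixed constants).
#' @param chol Lower-triangular n x n Choleski factor of the mixing
#'   covariance, or a length-n vector of standard deviations (expanded to a
#'   diagonal factor).
#' @param fixed_coeffs Named numeric vector of non-mixed coefficients
#'   (fixed alternative-specific constants and/or attribute coefficients).
#' @return An object of class `mixing_params`.
#' @export
mixing_params <- function(means, chol, fixed_coeffs = numeric(0)) {
  means <- unlist(means)
  n <- length(means)
  if (is.null(names(means)) && n > 0) names(means) <- paste0("dim", seq_len(n))
  if (is.vector(chol) && !is.matrix(chol)) chol <- diag(chol, nrow = length(chol))
  chol <- as.matrix(chol)
  if (n > 0 && (nrow(chol) != n || ncol(chol) != n))
    stop("chol must be n x n with n = length(means)")
  if (any(chol[upper.tri(chol)] != 0))
    stop("chol must be lower triangular")
  dimnames(chol) <- list(names(means), names(means))
  structure(list(means = means, chol = chol, fixed_coeffs = fixed_coeffs),
            class = "mixing_params")
}

#' Mixing parameters from a mean vector and covariance matrix
#'
#' Takes the lower-triangular Choleski factor of `cov` with non-negative
#' diagonal (the canonical quadrant).
#'
#' @param means Mixing means.
#' @param cov Mixing covariance matrix (symmetric positive semi-definite).
#' @param fixed_coeffs Non-mixed coefficients.
#' @return A [mixing_params()] object.
#' @export
params_from_moments <- function(means, cov, fixed_coeffs = numeric(0)) {
  cov <- as.matrix(cov)
  Q <- t(chol(cov))
  mixing_params(means, Q, fixed_coeffs)
}

#' @export
print.mixing_params <- function(x, ...) {
  cat("Mixing parameters (", length(x$means), " mixed dimension(s))\n", sep = "")
  cat("  means: ", paste(sprintf("%s=%.4g", names(x$means), x$means),
                         collapse = ", "), "\n")
  cat("  Choleski factor:\n")
  print(round(x$chol, 4))
  if (length(x$fixed_coeffs))
    cat("  fixed: ", paste(sprintf("%s=%.4g", names(x$fixed_coeffs),
                                   x$fixed_coeffs), collapse = ", "), "\n")
  invisible(x)
}

#' Conditional logit choice probabilities
#'
#' Softmax of a vector of systematic utilities, computed with max-subtraction
#' so large utilities cannot overflow. Invariant to adding a constant to all
#' utilities.
#'
#' @param systematic_utilities Numeric vector, one utility per alternative
#'   (the base alternative's utility is 0 by construction).
#' @return Probability vector summing to 1.
#' @export
logit_choice_prob <- function(systematic_utilities) {
  if (any(!is.finite(systematic_utilities)))
    stop("utilities must be finite")
  e <- exp(systematic_utilities - max(systematic_utilities))
  e / sum(e)
}

# Full coefficient vector for one beta: named utilities per alternative plus
# attribute part. beta covers every non-base alternative's constant and each
# attribute column.
.utilities_for_rows <- function(panel, rows, beta) {
  alt <- as.character(panel$data$alternative[rows])
  u <- numeric(length(rows))
  for (a in setdiff(panel$alternatives, panel$base_alternative))
    u[alt == a] <- u[alt == a] + beta[[a]]
  for (ac in panel$attr_cols)
    u <- u + panel$data[[ac]][rows] * beta[[ac]]
  u
}

#' Panel log-probability of one individual's choices given a coefficient draw
#'
#' Sum over the individual's choice situations of the log conditional-logit
#' probability of the chosen alternative, at a single coefficient vector.
#'
#' @param panel A [choice_panel()].
#' @param individual Individual identifier (as in the data).
#' @param beta Named coefficient vector: one constant per non-base
#'   alternative plus one coefficient per attribute column.
#' @return The log-probability (<= 0).
#' @export
panel_logprob_given_beta <- function(panel, individual, beta) {
  rows <- which(panel$data$individual == individual)
  if (!length(rows)) stop("unknown individual: ", individual)
  u <- .utilities_for_rows(panel, rows, beta)
  J <- panel$n_alternatives
  um <- matrix(u, nrow = J)                      # alternatives x situations
  ch <- matrix(panel$data$chosen[rows], nrow = J)
  mx <- apply(um, 2, max)
  lse <- mx + log(colSums(exp(sweep(um, 2, mx))))
  sum(um[ch == 1] - lse)
}

#' Transform a standard-normal draw into a coefficient draw
#'
#' `beta = b + Q z`: mean vector plus lower-triangular Choleski factor times
#' the standard-normal draw. In one dimension this is mean + sd * z.
#'
#' @param z Standard-normal draw vector (length n).
#' @param params A [mixing_params()].
#' @return Coefficient vector of length n.
#' @export
transform_draws <- function(z, params) {
  drop(params$means + params$chol %*% z)
}

#' Flip the sign of Choleski-factor columns
#'
#' Multiplies column `k` of `Q` by `signs[k]`. Every such flip leaves the
#' implied covariance `Q Q'` exactly unchanged, so the `2^n` sign patterns
#' index `2^n` equivalent factorizations ("quadrants") of one covariance
#' matrix; given a positive-diagonal input, the quadrant of the output is
#' read off its diagonal signs.
#'
#' @param chol Lower-triangular factor.
#' @param signs Vector of +1/-1, one per column.
#' @return The flipped lower-triangular factor.
#' @export
flip_factor <- function(chol, signs) {
  if (any(chol[upper.tri(chol)] != 0)) stop("chol must be lower triangular")
  if (!all(signs %in% c(-1, 1))) stop("signs must be +1 or -1")
  sweep(chol, 2, signs, `*`)
}

# ---- compiled panel representations -----------------------------------------

# ASC-only fast path: per-individual choice counts are sufficient statistics.
.compile_counts <- function(panel) {
  ch <- panel$data$chosen == 1
  C <- table(factor(panel$data$individual[ch], levels = panel$individuals),
             factor(as.character(panel$data$alternative[ch]),
                    levels = panel$alternatives))
  C <- matrix(as.numeric(C), nrow = length(panel$individuals),
              dimnames = dimnames(C))
  list(counts = C, T_i = rowSums(C))
}

# General path: row-level design, situations balanced with J rows each,
# ordered individual / situation / alternative.
.compile_general <- function(panel) {
  d <- panel$data
  J <- panel$n_alternatives
  S <- nrow(d) / J
  sit_first <- seq(1, nrow(d), by = J)
  sit_ind <- factor(d$individual[sit_first], levels = panel$individuals)
  chosen_pos <- ((which(d$chosen == 1) - 1L) %% J) + 1L
  row_ind <- match(d$individual, panel$individuals)
  list(J = J, S = S, sit_ind = sit_ind, chosen_pos = chosen_pos,
       row_ind = row_ind)
}

.compiled <- function(panel) {
  if (!is.null(panel$cache$cp)) return(panel$cache$cp)
  cp <- if (length(panel$attr_cols)) .compile_general(panel)
        else .compile_counts(panel)
  panel$cache$cp <- cp
  cp
}

# log(exp(a) + exp(b)) elementwise, -Inf safe
.logaddexp <- function(a, b) {
  m <- pmax(a, b)
  r <- m + log(exp(a - m) + exp(b - m))
  r[is.infinite(m) & m < 0] <- -Inf
  r
}

# Mixed coefficient matrices B_k = b_k + sum_m Q[k,m] Z_m, each I x Rb,
# for a draw-index block.
.mixed_coef_mats <- function(draws, params, cols) {
  n <- length(params$means)
  Q <- params$chol
  lapply(seq_len(n), function(k) {
    B <- matrix(params$means[[k]], nrow = dim(draws$points)[1],
                ncol = length(cols))
    for (m in seq_len(k))
      if (Q[k, m] != 0) B <- B + Q[k, m] * draws$points[, cols, m]
    B
  })
}

# Per-individual panel log-likelihood matrix L (I x Rb) for a draw block,
# ASC-only fast path.
.panel_ll_block_counts <- function(panel, cp, params, Bs) {
  I <- nrow(cp$counts); Rb <- ncol(Bs[[1]])
  mixed <- names(params$means)
  utils_of <- function(a) {
    if (a == panel$base_alternative) return(0)
    if (a %in% mixed) return(Bs[[match(a, mixed)]])
    params$fixed_coeffs[[a]]
  }
  Us <- lapply(panel$alternatives, utils_of)
  mx <- matrix(0, I, Rb)
  for (U in Us) mx <- pmax(mx, U)
  ssum <- matrix(0, I, Rb)
  for (U in Us) ssum <- ssum + exp(U - mx)
  L <- -(cp$T_i) * (mx + log(ssum))
  for (j in seq_along(Us))
    L <- L + cp$counts[, j] * Us[[j]]
  L
}

# General path with attributes: row-level utilities.
.panel_ll_block_general <- function(panel, cp, params, Bs) {
  d <- panel$data
  N <- nrow(d); J <- cp$J; S <- cp$S; Rb <- ncol(Bs[[1]])
  mixed <- names(params$means)
  u_fix <- numeric(N)
  alt <- as.character(d$alternative)
  for (a in setdiff(panel$alternatives, c(panel$base_alternative, mixed)))
    u_fix[alt == a] <- u_fix[alt == a] + params$fixed_coeffs[[a]]
  for (ac in panel$attr_cols)
    u_fix <- u_fix + d[[ac]] * params$fixed_coeffs[[ac]]
  U <- matrix(u_fix, N, Rb)
  for (k in seq_along(mixed)) {
    xk <- as.numeric(alt == mixed[k])
    U <- U + xk * Bs[[k]][cp$row_ind, , drop = FALSE]
  }
  dim(U) <- c(J, S, Rb)
  mx <- U[1, , , drop = TRUE]
  if (J > 1) for (j in 2:J) mx <- pmax(mx, U[j, , , drop = TRUE])
  ssum <- 0
  for (j in 1:J) ssum <- ssum + exp(U[j, , , drop = TRUE] - mx)
  base_idx <- (seq_len(S) - 1L) * J + cp$chosen_pos
  idx <- outer(base_idx, (seq_len(Rb) - 1L) * (J * S), `+`)
  u_ch <- matrix(U[idx], S, Rb)
  logp <- u_ch - mx - log(ssum)
  rowsum(logp, cp$sit_ind)
}

#' Simulated panel mixed logit log-likelihood
#'
#' Approximates each individual's mixed likelihood by averaging the panel
#' product of conditional-logit probabilities over `R` quasi-random
#' coefficient draws `beta_ir = b + Q z_ir`, and sums the log averages over
#' individuals. All panel products are kept in log space (per-individual
#' log-sum-exp over draws), so 20-fold probability products cannot underflow.
#' The result is deterministic given (panel, params, draws).
#'
#' With an empty mixing (`length(params$means) == 0`) this is the
#' conventional multinomial logit log-likelihood at the fixed coefficients,
#' and `draws` may be `NULL`.
#'
#' @param panel A [choice_panel()].
#' @param params A [mixing_params()]; mixed-dimension order must match the
#'   draw set's prime assignment.
#' @param draws A `normal_draw_set` from [build_draws()] with matching
#'   dimension and individual count.
#' @param chunk Maximum number of draw columns processed at once (memory
#'   control); default sizes the block to about 4e6 doubles.
#' @return The simulated log-likelihood (scalar). Individuals whose averaged
#'   simulated probability underflows to zero are reported by id in a
#'   warning.
#' @export
simulated_loglik <- function(panel, params, draws, chunk = NULL) {
  stopifnot(inherits(panel, "choice_panel"), inherits(params, "mixing_params"))
  n <- length(params$means)
  if (n == 0L) {
    ll <- sum(vapply(panel$individuals, function(i)
      panel_logprob_given_beta(panel, i, params$fixed_coeffs), numeric(1)))
    return(ll)
  }
  stopifnot(inherits(draws, "normal_draw_set"))
  dm <- dim(draws$points)
  if (dm[3] != n) stop("draw set dimension (", dm[3],
                       ") does not match mixing dimension (", n, ")")
  if (dm[1] != panel$n_individuals)
    stop("draw set has ", dm[1], " individuals, panel has ",
         panel$n_individuals)
  I <- dm[1]; R <- dm[2]
  cp <- .compiled(panel)
  fast <- length(panel$attr_cols) == 0L
  if (is.null(chunk)) {
    per_col <- if (fast) I else nrow(panel$data)
    chunk <- max(1L, min(R, as.integer(4e6 / per_col)))
  }
  ls <- rep(-Inf, I)
  start <- 1L
  while (start <= R) {
    cols <- start:min(R, start + chunk - 1L)
    Bs <- .mixed_coef_mats(draws, params, cols)
    L <- if (fast) .panel_ll_block_counts(panel, cp, params, Bs)
         else .panel_ll_block_general(panel, cp, params, Bs)
    m <- apply(L, 1, max)
    block_ls <- ifelse(is.finite(m),
                       m + log(rowSums(exp(L - m))), -Inf)
    ls <- .logaddexp(ls, block_ls)
    start <- start + chunk
  }
  bad <- !is.finite(ls)
  if (any(bad))
    warning("simulated probability underflowed to zero for individual(s): ",
            paste(panel$individuals[bad], collapse = ", "))
  sum(ls - log(R))
}

#' Simulated log mixing-average of an arbitrary kernel
#'
#' Diagnostic evaluator isolating the source of quadrant asymmetry: averages
#' `exp(log_kernel(beta))` over the transformed draws of each individual and
#' sums the logs. With a kernel symmetric in `beta` (e.g. proportional to
#' `exp(-sum(beta^2))`) the result is invariant to Choleski sign flips even
#' for conventional, asymmetric draws — demonstrating that the quadrant
#' differences of the logit model come from kernel asymmetry meeting draw
#' asymmetry.
#'
#' @param draws A `normal_draw_set`.
#' @param params A [mixing_params()].
#' @param log_kernel Function taking a coefficient vector and returning a log
#'   kernel value.
#' @return Sum over individuals of the log draw-average of the kernel.
#' @export
simulated_kernel_loglik <- function(draws, params, log_kernel) {
  dm <- dim(draws$points)
  total <- 0
  for (i in seq_len(dm[1])) {
    lk <- vapply(seq_len(dm[2]), function(r)
      log_kernel(transform_draws(draws$points[i, r, ], params)), numeric(1))
    m <- max(lk)
    total <- total + m + log(mean(exp(lk - m)))
  }
  total
}

#' All sign patterns for n dimensions
#'
#' @param n Number of dimensions.
#' @return 2^n x n matrix of +1/-1, base pattern (all +1) first, in
#'   binary-mask order (bit k flips dimension k).
#' @export
quadrant_signs <- function(n) {
  K <- 2L^n
  s <- matrix(1, K, n)
  for (mask in 0:(K - 1L))
    for (k in seq_len(n))
      if (bitwAnd(mask, bitwShiftL(1L, k - 1L)) != 0L) s[mask + 1L, k] <- -1
  s
}

.quadrant_label <- function(signs) {
  paste0(ifelse(signs > 0, "+", "-"), collapse = "")
}

#' Evaluate the simulated log-likelihood in every Choleski sign quadrant
#'
#' Evaluates [simulated_loglik()] at all `2^n` column-sign-flipped versions of
#' `params$chol`, using the *same* draw set throughout, and reports the
#' largest absolute pairwise difference. With fully antithetic draws the
#' difference is zero up to floating-point noise; with conventional Halton
#' draws it can reach several log-likelihood units at practical draw counts.
#'
#' @param panel A [choice_panel()].
#' @param params A [mixing_params()] whose Choleski diagonal is non-negative
#'   (the canonical quadrant).
#' @param draws A `normal_draw_set`.
#' @return An object of class `quadrant_scan_report`: `per_quadrant_ll`
#'   (named vector, one entry per sign pattern), `signs` (pattern matrix) and
#'   `max_abs_difference`.
#' @export
quadrant_scan <- function(panel, params, draws) {
  n <- length(params$means)
  if (n < 1L) stop("quadrant scan requires at least one mixed dimension")
  if (any(diag(params$chol) < 0))
    stop("params$chol must be in the canonical quadrant (non-negative diagonal)")
  S <- quadrant_signs(n)
  ll <- numeric(nrow(S))
  for (q in seq_len(nrow(S))) {
    pq <- params
    pq$chol <- flip_factor(params$chol, S[q, ])
    ll[q] <- simulated_loglik(panel, pq, draws)
  }
  names(ll) <- apply(S, 1, .quadrant_label)
  structure(list(per_quadrant_ll = ll, signs = S,
                 max_abs_difference = max(ll) - min(ll)),
            class = "quadrant_scan_report")
}

#' @export
print.quadrant_scan_report <- function(x, ...) {
  cat("Quadrant scan over", length(x$per_quadrant_ll),
      "sign-flipped Choleski factorizations\n")
  print(round(x$per_quadrant_ll, 6))
  cat("max |difference|:", format(x$max_abs_difference, digits = 6), "\n")
  invisible(x)
}
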