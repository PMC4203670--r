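# Shared fixtures, all generated in code.

# Small 4-alternative panel with 3 mixed constants.
small_sim <- function(I = 30, T_ = 5, seed = 3, ...) {
  simulate_panel(sim_spec(n_individuals = I, n_situations = T_,
                          n_alternatives = 4, seed = seed, ...))
}

# Two-alternative single-choice toy panel (one individual).
toy_panel <- function() {
  choice_panel(data.frame(individual = 1, situation = 1,
                          alternative = c("A", "B"), chosen = c(0, 1)),
               base_alternative = "A")
}

std_cfg <- function(I, R, mode = "full", n = 3, drop = 10) {
  nm <- c("B", "C", "D")[seq_len(n)]
  draw_config(primes = stats::setNames(c(2, 3, 5)[seq_len(n)], nm),
              draws_per_individual = R, n_individuals = I,
              antithetic = mode, drop = drop)
}

# Independent digit-expansion oracle for the radical inverse: builds the
# digit list explicitly, then sums digits over descending powers.
digit_reversal_oracle <- function(index, base) {
  digits <- integer(0)
  while (index > 0) {
    digits <- c(digits, index %% base)
    index <- index %/% base
  }
  sum(digits / base^seq_along(digits))
}
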