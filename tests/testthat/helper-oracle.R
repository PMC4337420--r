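# Independent oracles and fixture builders, kept deliberately naive.
#
# The dense-grid oracle enumerates every candidate breakpoint at a fixed
# resolution and solves each conditional OLS with base QR (lm.fit) — a
# different computational path from the package's suffix-sum profile with
# coarse-grid + local refinement.

oracle_rss <- function(x, y, taus) {
  ux <- sort(unique(x))
  vapply(taus, function(tau) {
    iu <- sum(ux <= tau)
    if (iu < 2L || (length(ux) - iu) < 2L) return(Inf)
    f <- lm.fit(cbind(1, x, pmax(0, x - tau)), y)
    sum(f$residuals^2)
  }, numeric(1))
}

# exhaustive minimiser on a dense grid between 2nd-smallest / 2nd-largest age
oracle_tau <- function(x, y, step = 0.01) {
  ux <- sort(unique(x))
  taus <- seq(ux[2L], ux[length(ux) - 1L], by = step)
  r <- oracle_rss(x, y, taus)
  taus[which.min(r)]
}

# exact piecewise-linear cohort (no noise)
make_piecewise <- function(ages = seq(0, 20, 2), each = 3, tau = 8,
                           b0 = 50, pre = -2, post = 0, group = "exact") {
  age <- rep(ages, each = each)
  ttp <- b0 + pre * age + (post - pre) * pmax(0, age - tau)
  data.frame(larva_id = seq_along(age), group = group, age = age, ttp = ttp,
             pupariated = TRUE, stringsAsFactors = FALSE)
}

# brute-force checker that a letter assignment is consistent with a
# significance matrix: significant pairs share no letter, pairs declared
# non-significant share at least one
check_letters_consistent <- function(letter_strings, sig, compared = NULL) {
  s <- length(letter_strings)
  sets <- lapply(letter_strings, function(l) strsplit(l, "")[[1]])
  for (i in seq_len(s - 1L)) for (j in (i + 1L):s) {
    if (!is.null(compared) && !compared[i, j]) next
    shared <- length(intersect(sets[[i]], sets[[j]])) > 0L
    if (sig[i, j] && shared) return(FALSE)
    if (!sig[i, j] && !shared) return(FALSE)
  }
  TRUE
}

tmp_csv <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  f
}

`%||%` <- function(a, b) if (is.null(a)) b else a
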