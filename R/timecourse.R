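# Relative qPCR quantification and sliding-window letter comparisons of
# time-course means.

#' Relative expression by the comparative Ct method
#'
#' Normalises each replicate's target Ct against the internal control measured
#' on the same sample (e.g. *RpL3*), then against a calibrator condition so
#' that the calibrator's mean relative expression is exactly 1 — the study's
#' convention of "fixing the values at 0 hr in the control genotype as 1".
#'
#' Per replicate, \eqn{\Delta Ct = Ct_{target} - Ct_{reference}} and the raw
#' relative quantity is \eqn{2^{-\Delta Ct}} (amplification efficiency fixed
#' at 2, i.e. perfect doubling per cycle). With the default
#' `average = "linear"` each value is divided by the *mean raw quantity* of
#' the calibrator replicates, which makes the calibrator's arithmetic mean 1
#' exactly. `average = "ct"` instead subtracts the calibrator's mean
#' \eqn{\Delta Ct} in the exponent (the classical \eqn{\Delta\Delta Ct}
#' form); that fixes the calibrator's *geometric* mean at 1.
#'
#' @param ct data frame of Ct records (`gene`, `group`, `time`, `replicate`,
#'   `ct_target`, `ct_reference`), e.g. from [read_ct_table()] or
#'   [simulate_qpcr()].
#' @param calibrator list with elements `group` and `time` naming the
#'   calibrator condition (applied per gene).
#' @param average `"linear"` (default) or `"ct"`; see Details.
#' @return data frame with columns `gene`, `group`, `time`, `replicate`,
#'   `value` (fold change, positive).
#' @examples
#' ct <- data.frame(gene = "phm", group = "ctrl", time = c(0, 0, 8),
#'                  replicate = c(1, 2, 1),
#'                  ct_target = c(25, 25, 23), ct_reference = c(18, 18, 18))
#' relative_expression(ct, calibrator = list(group = "ctrl", time = 0))
#' @export
relative_expression <- function(ct, calibrator, average = c("linear", "ct")) {
  average <- match.arg(average)
  ct <- as.data.frame(ct)
  stopifnot(all(c("gene", "time", "ct_target", "ct_reference") %in% names(ct)))
  if (!"group" %in% names(ct)) ct$group <- "unknown"
  if (!"replicate" %in% names(ct)) ct$replicate <- seq_len(nrow(ct))
  if (!is.list(calibrator) || is.null(calibrator$group) || is.null(calibrator$time))
    stop_cw("calibrator must be list(group = ..., time = ...)", "cw_config_error")
  bad <- which(!is.finite(ct$ct_target) | !is.finite(ct$ct_reference))
  if (length(bad))
    stop_cw(sprintf("missing target or reference Ct at row %d", bad[1L]),
            "cw_parse_error")

  dct <- ct$ct_target - ct$ct_reference
  out <- vector("list", 0L)
  for (g in unique(ct$gene)) {
    sel <- ct$gene == g
    cal <- sel & ct$group == calibrator$group &
      abs(ct$time - calibrator$time) < 1e-8
    if (!any(cal))
      stop_cw(sprintf("calibrator condition (%s, %g hr) absent for gene '%s'",
                      calibrator$group, calibrator$time, g), "cw_config_error")
    value <- if (average == "linear") {
      2^(-dct[sel]) / mean(2^(-dct[cal]))
    } else {
      2^(-(dct[sel] - mean(dct[cal])))
    }
    out[[g]] <- data.frame(gene = g, group = ct$group[sel], time = ct$time[sel],
                           replicate = ct$replicate[sel], value = value,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# ---- compact letter display ------------------------------------------------

# Insert-and-absorb letter assignment from a significance relation.
# `sig` is an s x s logical matrix (TRUE = the pair differs significantly).
# Returns a list of character vectors of item indices per letter column.
# Guarantees: significant pairs never share a column; pairs never declared
# significant always share at least one column they started in together.
letters_from_sig <- function(sig) {
  s <- nrow(sig)
  cols <- list(seq_len(s))
  pairs <- which(sig & upper.tri(sig), arr.ind = TRUE)
  if (nrow(pairs)) {
    for (k in seq_len(nrow(pairs))) {
      i <- pairs[k, 1L]; j <- pairs[k, 2L]
      newcols <- list()
      for (col in cols) {
        if (i %in% col && j %in% col) {
          newcols <- c(newcols, list(setdiff(col, i)), list(setdiff(col, j)))
        } else {
          newcols <- c(newcols, list(col))
        }
      }
      # absorb: drop columns that are subsets of another column
      keep <- rep(TRUE, length(newcols))
      for (u in seq_along(newcols)) {
        for (v in seq_along(newcols)) {
          if (u != v && keep[u] && keep[v] &&
              all(newcols[[u]] %in% newcols[[v]]) &&
              (length(newcols[[u]]) < length(newcols[[v]]) || u > v)) {
            keep[u] <- FALSE
            break
          }
        }
      }
      cols <- newcols[keep]
    }
  }
  # deterministic letter order: lexicographic in column membership
  ord <- order(vapply(cols, function(col)
    paste(sprintf("%06d", sort(col)), collapse = ","), character(1)))
  cols[ord]
}

letter_symbols <- function(k) {
  base <- letters
  if (k <= length(base)) return(base[seq_len(k)])
  extra <- as.vector(outer(base, base, paste0))
  c(base, extra)[seq_len(k)]
}

#' Sliding-window letter groups for a time course
#'
#' Implements the figure-legend convention "points sharing the same letter
#' indicate the mean at the time ±2 hr are statistically indistinguishable":
#' cell means (one cell per group × time) are compared pairwise by Welch's
#' t-test, but only between cells of the same group whose times differ by at
#' most `window` hours, and between cells of different groups at matched
#' times. Letters are then assigned with the insert-and-absorb
#' compact-letter-display algorithm so that every significant pair shares no
#' letter and every compared, non-significant pair shares at least one.
#'
#' @param samples data frame with columns `group`, `time`, `replicate`,
#'   `value` (e.g. 20E titres in pg/mg, or relative expression), e.g. from
#'   [read_timecourse_table()] or [relative_expression()] (rename `value`).
#' @param window half-width of the comparison window in hours (default 2,
#'   the study's sampling interval).
#' @param alpha significance level for the pairwise decisions (default 0.05).
#' @param all_pairs compare every pair of cells regardless of time distance.
#' @param p_adjust `"none"` (default; the study applies no correction) or
#'   `"holm"` across the compared pairs.
#' @return Object of class `letter_display`: data frame with columns `group`,
#'   `time`, `n`, `mean`, `sem`, `letters`, plus attributes `alpha` and
#'   `decisions` (the compared pairs with p-values). Cells with fewer than two
#'   replicates are excluded with a warning.
#' @examples
#' tc <- data.frame(group = "w1118",
#'                  time = rep(c(0, 2, 4), each = 3),
#'                  replicate = rep(1:3, 3),
#'                  value = c(1, 1.1, 0.9, 1.2, 1.0, 1.1, 5.1, 4.8, 5.3))
#' windowed_letter_groups(tc)
#' @export
windowed_letter_groups <- function(samples, window = 2, alpha = 0.05,
                                   all_pairs = FALSE,
                                   p_adjust = c("none", "holm")) {
  p_adjust <- match.arg(p_adjust)
  samples <- as.data.frame(samples)
  stopifnot(all(c("group", "time", "value") %in% names(samples)))
  key <- interaction(samples$group, samples$time, drop = TRUE, sep = "\r")
  cells <- split(samples, key)
  sizes <- vapply(cells, nrow, integer(1))
  if (any(sizes < 2L)) {
    warn_cw(sprintf("%d cell(s) with < 2 replicates excluded from letter grouping",
                    sum(sizes < 2L)), "cw_small_cell_warning")
    cells <- cells[sizes >= 2L]
  }
  if (length(cells) < 2L)
    stop_cw("need at least 2 (group, time) cells with >= 2 replicates",
            "cw_config_error")
  info <- data.frame(
    group = vapply(cells, function(d) as.character(d$group[1L]), character(1)),
    time = vapply(cells, function(d) d$time[1L], numeric(1)),
    n = vapply(cells, nrow, integer(1)),
    mean = vapply(cells, function(d) mean(d$value), numeric(1)),
    sem = vapply(cells, function(d) sd(d$value) / sqrt(nrow(d)), numeric(1)),
    stringsAsFactors = FALSE
  )
  ord <- order(info$group, info$time)
  info <- info[ord, , drop = FALSE]
  cells <- cells[ord]
  rownames(info) <- NULL
  s <- nrow(info)

  compare <- function(i, j) {
    if (all_pairs) return(TRUE)
    same_group <- info$group[i] == info$group[j]
    dt <- abs(info$time[i] - info$time[j])
    (same_group && dt <= window + 1e-8) || (!same_group && dt < 1e-8)
  }
  pr <- list()
  for (i in seq_len(s - 1L)) for (j in (i + 1L):s) {
    if (!compare(i, j)) next
    p <- tryCatch(t.test(cells[[i]]$value, cells[[j]]$value)$p.value,
                  error = function(e) NA_real_)
    # identical constant cells: no variance, no evidence of difference
    if (is.na(p)) p <- if (isTRUE(all.equal(mean(cells[[i]]$value),
                                            mean(cells[[j]]$value)))) 1 else 0
    pr[[length(pr) + 1L]] <- data.frame(i = i, j = j, p = p)
  }
  decisions <- if (length(pr)) do.call(rbind, pr) else
    data.frame(i = integer(), j = integer(), p = numeric())
  if (p_adjust == "holm" && nrow(decisions))
    decisions$p <- stats::p.adjust(decisions$p, method = "holm")
  decisions$significant <- decisions$p < alpha

  sig <- matrix(FALSE, s, s)
  if (nrow(decisions)) {
    sig[cbind(decisions$i, decisions$j)] <- decisions$significant
    sig[cbind(decisions$j, decisions$i)] <- decisions$significant
  }
  cols <- letters_from_sig(sig)
  syms <- letter_symbols(length(cols))
  info$letters <- vapply(seq_len(s), function(i)
    paste0(syms[vapply(cols, function(col) i %in% col, logical(1))],
           collapse = ""), character(1))

  decisions$group_i <- info$group[decisions$i]
  decisions$time_i <- info$time[decisions$i]
  decisions$group_j <- info$group[decisions$j]
  decisions$time_j <- info$time[decisions$j]
  structure(info, class = c("letter_display", "data.frame"),
            alpha = alpha, window = window, decisions = decisions)
}

#' @export
print.letter_display <- function(x, ...) {
  cat(sprintf("Time-course letter groups (window +/- %g hr, alpha = %g)\n",
              attr(x, "window"), attr(x, "alpha")))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
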