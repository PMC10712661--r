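## Cross-phase comparison stage: per feature and per arousal session (or
## valence half), Shapiro-Wilk normality per phase, the subject-blocked
## Friedman test across the three stimulation phases, and - only when the
## omnibus test is significant - pairwise comparison of phase mean ranks
## with a Tukey-type (studentized range) familywise correction.

#' Assemble a tidy feature table
#'
#' One value per row, keyed by subject, phase, arousal session, segment
#' (`"whole"`, `"low"` or `"high"`) and feature name.
#'
#' @param subject,phase,session,segment,feature,value vectors of equal
#'   length (recycled where scalar).
#' @return a `feature_table` data.frame.
#' @export
feature_table <- function(subject, phase, session, segment, feature, value) {
  out <- data.frame(subject = subject, phase = phase, session = session,
                    segment = segment, feature = feature, value = value,
                    stringsAsFactors = FALSE)
  key <- do.call(paste, c(out[c("subject", "phase", "session", "segment",
                                "feature")], sep = "\r"))
  if (anyDuplicated(key)) stop("duplicate (subject, phase, session, segment, feature) keys")
  class(out) <- c("feature_table", "data.frame")
  out
}

ft_slice <- function(table, feature, session, segment = "whole") {
  table[table$feature == feature & table$session == session &
          table$segment == segment, , drop = FALSE]
}

# subject x phase value matrix for one (feature, session, segment) key
ft_blocks <- function(table, feature, session, segment = "whole",
                      phases = PHASES) {
  s <- ft_slice(table, feature, session, segment)
  subj <- sort(unique(s$subject))
  m <- matrix(NA_real_, length(subj), length(phases),
              dimnames = list(as.character(subj), phases))
  for (i in seq_len(nrow(s)))
    m[as.character(s$subject[i]), s$phase[i]] <- s$value[i]
  m
}

#' Per-phase Shapiro-Wilk normality scan
#'
#' @param table a [feature_table()].
#' @param feature,session,segment the comparison key.
#' @param min_n minimum group size.
#' @return data.frame with one row per phase: `phase`, `W`, `p`, `normal`
#'   (at 0.05). Degenerate groups (constant, or fewer than `min_n` values)
#'   are `NA`-marked with a warning.
#' @export
normality_scan <- function(table, feature, session, segment = "whole",
                           min_n = 3) {
  m <- ft_blocks(table, feature, session, segment)
  res <- lapply(colnames(m), function(ph) {
    v <- m[, ph]; v <- v[is.finite(v)]
    if (length(v) < min_n || stats::sd(v) == 0) {
      warning(sprintf("phase %s: too few or constant values; normality NA", ph))
      return(data.frame(phase = ph, W = NA_real_, p = NA_real_, normal = NA))
    }
    sw <- stats::shapiro.test(v)
    data.frame(phase = ph, W = unname(sw$statistic), p = sw$p.value,
               normal = sw$p.value > 0.05)
  })
  do.call(rbind, res)
}

#' Friedman test across the three phases
#'
#' Subject-blocked rank test on the phases; subjects missing any phase are
#' dropped (complete-block requirement) and counted.
#'
#' @param table a [feature_table()].
#' @param feature,session,segment the comparison key.
#' @param min_blocks minimum complete blocks required.
#' @return list with `stat` (chi-square), `p`, `df`, `n_blocks`,
#'   `n_dropped`, and the complete-block matrix `blocks`.
#' @export
friedman_across_phases <- function(table, feature, session,
                                   segment = "whole", min_blocks = 5) {
  m <- ft_blocks(table, feature, session, segment)
  cc <- stats::complete.cases(m) & apply(is.finite(m), 1, all)
  dropped <- sum(!cc)
  m <- m[cc, , drop = FALSE]
  if (nrow(m) < min_blocks)
    stop(sprintf("only %d complete blocks (need >= %d)", nrow(m), min_blocks))
  ranks <- t(apply(m, 1, rank))
  if (all(apply(ranks, 1, function(r) all(r == r[1])))) {
    # every block fully tied: no rank variation, nothing to test
    return(list(stat = 0, p = 1, df = ncol(m) - 1, n_blocks = nrow(m),
                n_dropped = dropped, blocks = m))
  }
  ft <- stats::friedman.test(m)
  list(stat = unname(ft$statistic), p = ft$p.value,
       df = unname(ft$parameter), n_blocks = nrow(m), n_dropped = dropped,
       blocks = m)
}

#' Tukey-type post-hoc pairwise comparison after Friedman
#'
#' Compares phase mean ranks pairwise; the difference is referred to the
#' studentized range distribution (the behavior of common `multcompare`
#' implementations): for phases a, b the statistic is
#' `q = |Rbar_a - Rbar_b| / sqrt(k(k+1)/(12 n)) ` and the familywise
#' p-value is `ptukey(q, k, Inf)`. Calling this without a significant
#' omnibus result is a contract error (the gatekeeping of the analysis).
#'
#' @param friedman result of [friedman_across_phases()].
#' @param alpha familywise significance level.
#' @return data.frame with one row per pair: `phase_a`, `phase_b`,
#'   `mean_rank_diff`, `corrected_p`, `significant`.
#' @export
posthoc_pairwise <- function(friedman, alpha = 0.05) {
  if (!is.finite(friedman$p) || friedman$p >= alpha)
    stop("post-hoc comparison requires a significant omnibus Friedman test")
  m <- friedman$blocks
  k <- ncol(m); n <- nrow(m)
  ranks <- t(apply(m, 1, rank))
  mr <- colMeans(ranks)
  se <- sqrt(k * (k + 1) / (12 * n))
  pairs <- utils::combn(colnames(m), 2)
  out <- lapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    q <- abs(mr[a] - mr[b]) / se
    p <- stats::ptukey(q * sqrt(2), nmeans = k, df = Inf, lower.tail = FALSE)
    data.frame(phase_a = a, phase_b = b,
               mean_rank_diff = unname(mr[a] - mr[b]),
               corrected_p = p, significant = p < alpha)
  })
  do.call(rbind, out)
}

#' Full comparison for one feature key
#'
#' Runs the normality scan, the Friedman omnibus test and - only when the
#' omnibus is significant at `alpha` - the Tukey-type pairwise stage.
#'
#' @param table a [feature_table()].
#' @param feature,session,segment the comparison key; `segment` `"whole"`
#'   compares entire arousal sessions (the arousal dimension), `"low"` or
#'   `"high"` compares valence halves (the valence dimension).
#' @param alpha significance level.
#' @return a `comparison_result` list: `feature`, `dimension`, `session`,
#'   `segment`, `normality`, `friedman_stat`, `friedman_p`, `pairwise`
#'   (NULL unless the omnibus is significant).
#' @export
compare_feature <- function(table, feature, session, segment = "whole",
                            alpha = 0.05) {
  nm <- suppressWarnings(normality_scan(table, feature, session, segment))
  fr <- friedman_across_phases(table, feature, session, segment)
  pw <- if (is.finite(fr$p) && fr$p < alpha) posthoc_pairwise(fr, alpha) else NULL
  structure(list(feature = feature,
                 dimension = if (segment == "whole") "arousal" else "valence",
                 session = session, segment = segment,
                 normality = nm,
                 friedman_stat = fr$stat, friedman_p = fr$p,
                 n_blocks = fr$n_blocks, n_dropped = fr$n_dropped,
                 pairwise = pw, alpha = alpha),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison> %s | session %s | %s (%s): chi2 = %.3f, p = %.4g\n",
              x$feature, x$session, x$dimension, x$segment,
              x$friedman_stat, x$friedman_p))
  if (!is.null(x$pairwise)) {
    for (i in seq_len(nrow(x$pairwise)))
      cat(sprintf("  %s vs %s: p = %.4g%s\n", x$pairwise$phase_a[i],
                  x$pairwise$phase_b[i], x$pairwise$corrected_p[i],
                  if (x$pairwise$significant[i]) " *" else ""))
  }
  invisible(x)
}

#' Read/write a tidy feature table as a delimited file
#' @param table a [feature_table()].
#' @param path file path (tab-separated).
#' @export
write_feature_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  feature_table(d$subject, d$phase, d$session, d$segment, d$feature, d$value)
}
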