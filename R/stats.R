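# Summary statistics: rates, Fisher's exact test, Student's t.

#' A rate with its counts
#'
#' @param num numerator (events).
#' @param den denominator (event set size).
#' @return list with `num`, `den`, `percent` (`NA` when `den == 0`:
#'   undefined, not 0).
#' @export
rate <- function(num, den) {
  list(num = as.integer(num), den = as.integer(den),
       percent = if (den > 0) 100 * num / den else NA_real_)
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p by the minimum-likelihood rule: the sum of
#' hypergeometric probabilities of all tables with the observed margins
#' whose probability does not exceed that of the observed table (within
#' an absolute tolerance of 1e-12).
#'
#' @param a,b,c,d cell counts, or `a` a 2x2 matrix.
#' @return two-sided p-value; `NA` with a warning when a margin is zero.
#' @export
fisher_exact <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) {
    stopifnot(all(dim(a) == 2))
    b <- a[1, 2]; c <- a[2, 1]; d <- a[2, 2]; a <- a[1, 1]
  }
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("cell counts must be nonnegative integers")
  }
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  if (min(r1, r2, c1, c2) == 0) {
    # a zero row or column admits a single table; conventionally p = 1,
    # but flag it as degenerate
    warning("Fisher's exact test undefined for zero margin; returning 1")
    return(1)
  }
  k <- max(0, c1 - r2):min(c1, r1)
  probs <- stats::dhyper(k, r1, r2, c1)
  p_obs <- stats::dhyper(a, r1, r2, c1)
  min(1, sum(probs[probs <= p_obs + 1e-12]))
}

#' Pooled-variance Student's t-test
#'
#' Classic two-sample Student's t with pooled variance and n1 + n2 - 2
#' degrees of freedom, two-sided p from the t distribution. With zero
#' pooled variance: p = 1 when the means are equal, p = 0 (t infinite)
#' otherwise.
#'
#' @param x,y numeric samples, each of size >= 2.
#' @return list with `t`, `df`, `p`, and the two sample means.
#' @export
students_t <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) stop("each sample must have at least 2 values")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / df
  dm <- mean(x) - mean(y)
  if (sp2 == 0) {
    tstat <- if (dm == 0) 0 else sign(dm) * Inf
    p <- if (dm == 0) 1 else 0
  } else {
    tstat <- dm / sqrt(sp2 * (1 / n1 + 1 / n2))
    p <- 2 * stats::pt(-abs(tstat), df)
  }
  list(t = tstat, df = df, p = p, mean_x = mean(x), mean_y = mean(y))
}

#' Summarise classified light-related turn events
#'
#' Computes the summary statistics of the assay from classified and
#' scored events: the cast-count frequency distribution (1 / 2 / >= 3
#' casts), success rates of 1-cast and n-cast turns and the per-larva
#' escape rate, first- and second-cast success / acceptance / rejection
#' rates, per-ordinal success within n-cast turns, head-cast amplitude
#' samples by ordinal and acceptance class, and the associated exact and
#' t tests. Only light-related turns (and their casts) enter the report;
#' percentages are exact count ratios, rounded only at presentation.
#'
#' @param turns turn table pooled over trials (from [classify_trial()] /
#'   [run_pipeline()]).
#' @param casts cast table pooled over trials.
#' @param trials per-trial table with columns `trial_id`, `escaped`.
#' @return list of class `larva_summary`; rates are [rate()] objects.
#' @export
summarize_turns <- function(turns, casts, trials) {
  rel <- turns[turns$light_related %in% TRUE, , drop = FALSE]
  key <- function(df) paste(df$trial_id, df$turn_id)
  casts <- casts[!is.na(casts$turn_id) & key(casts) %in% key(rel), ,
                 drop = FALSE]
  casts$kind <- rel$kind[match(key(casts), key(rel))]

  one <- rel[rel$kind == "1-cast", , drop = FALSE]
  nca <- rel[rel$kind == "n-cast", , drop = FALSE]
  n_turns <- nrow(rel)

  firsts <- casts[casts$ordinal == 1, , drop = FALSE]
  seconds <- casts[casts$ordinal == 2, , drop = FALSE]
  f1 <- firsts[firsts$kind == "1-cast", , drop = FALSE]
  fn <- firsts[firsts$kind == "n-cast", , drop = FALSE]
  failed_first <- firsts[!firsts$success, , drop = FALSE]
  succ_first <- firsts[firsts$success, , drop = FALSE]
  failed_second <- seconds[!seconds$success, , drop = FALSE]
  succ_second <- seconds[seconds$success, , drop = FALSE]

  esc <- trials$escaped[!is.na(trials$escaped)]

  ncasts_all <- casts[casts$kind == "n-cast", , drop = FALSE]
  ord_bin <- function(o) ifelse(o == 1, "1st", ifelse(o == 2, "2nd", ">=3rd"))
  amp_bin <- function(o) ifelse(o >= 5, ">=5th", paste0(o, c("st", "nd", "rd",
                                                             "th")[pmin(o, 4)]))

  succ_rate <- function(df) rate(sum(df$success), nrow(df))
  acc_rate <- function(df) rate(sum(df$acceptance == "accepted"), nrow(df))
  rej_rate <- function(df) rate(sum(df$acceptance == "rejected"), nrow(df))

  report <- list(
    n_turns = n_turns,
    composition = list(
      one_cast = rate(nrow(one), n_turns),
      two_cast = rate(sum(rel$n_casts == 2), n_turns),
      three_plus_cast = rate(sum(rel$n_casts >= 3), n_turns)
    ),
    success = list(
      one_cast = succ_rate(one),
      n_cast = succ_rate(nca),
      all_turns = succ_rate(rel),
      escape = rate(sum(esc), length(esc))
    ),
    first_cast_success = list(
      one_cast = succ_rate(f1),
      n_cast = succ_rate(fn),
      pooled = succ_rate(firsts)
    ),
    failed_first = list(
      rejected = rej_rate(failed_first),
      accepted = acc_rate(failed_first)
    ),
    successful_first = list(
      accepted = acc_rate(succ_first),
      rejected = rej_rate(succ_first)
    ),
    failed_second = list(rejected = rej_rate(failed_second)),
    successful_second = list(accepted = acc_rate(succ_second)),
    ncast_ordinal_success = list(
      first = succ_rate(ncasts_all[ncasts_all$ordinal == 1, , drop = FALSE]),
      second = succ_rate(ncasts_all[ncasts_all$ordinal == 2, , drop = FALSE]),
      third_plus = succ_rate(ncasts_all[ncasts_all$ordinal >= 3, ,
                                        drop = FALSE])
    ),
    amplitudes = if (nrow(casts) > 0) {
      data.frame(trial_id = casts$trial_id, turn_id = casts$turn_id,
                 kind = casts$kind, ordinal = casts$ordinal,
                 ordinal_bin = amp_bin(casts$ordinal),
                 acceptance = casts$acceptance, success = casts$success,
                 amplitude = casts$amplitude, stringsAsFactors = FALSE)
    } else {
      data.frame()
    },
    heading_angles = if (nrow(rel) > 0) {
      data.frame(trial_id = rel$trial_id, turn_id = rel$turn_id,
                 kind = rel$kind, heading_angle = rel$heading_angle,
                 stringsAsFactors = FALSE)
    } else {
      data.frame()
    }
  )

  # significance tests mirroring the figure comparisons; undefined (zero
  # margin) comparisons are omitted rather than forced
  tests <- list()
  safe_fisher <- function(a, b, c, d) {
    if (min(a + b, c + d, a + c, b + d) == 0) NA_real_
    else fisher_exact(a, b, c, d)
  }
  if (nrow(one) > 0 && nrow(nca) > 0) {
    tests$success_one_vs_n <- safe_fisher(
      sum(one$success), sum(!one$success),
      sum(nca$success), sum(!nca$success))
    tests$first_success_one_vs_n <- safe_fisher(
      sum(f1$success), sum(!f1$success),
      sum(fn$success), sum(!fn$success))
  }
  a1 <- ncasts_all$amplitude[ncasts_all$ordinal == 1]
  a2 <- ncasts_all$amplitude[ncasts_all$ordinal == 2]
  if (length(a1) >= 2 && length(a2) >= 2) {
    tests$amplitude_first_vs_second <- students_t(a1, a2)
  }
  fa <- failed_first$amplitude[failed_first$acceptance == "accepted"]
  fr <- failed_first$amplitude[failed_first$acceptance == "rejected"]
  if (length(fa) >= 2 && length(fr) >= 2) {
    tests$failed_first_accepted_vs_rejected <- students_t(fa, fr)
  }
  report$tests <- tests
  class(report) <- "larva_summary"
  report
}

#' @export
print.larva_summary <- function(x, ...) {
  fmt <- function(r) {
    if (is.na(r$percent)) sprintf("undefined (0 events)")
    else sprintf("%.2f%% (%d/%d)", r$percent, r$num, r$den)
  }
  cat("<larva_summary>", x$n_turns, "light-related turns\n")
  cat("  composition: 1-cast", fmt(x$composition$one_cast),
      "| 2-cast", fmt(x$composition$two_cast),
      "| >=3-cast", fmt(x$composition$three_plus_cast), "\n")
  cat("  turn success: 1-cast", fmt(x$success$one_cast),
      "| n-cast", fmt(x$success$n_cast),
      "| escape", fmt(x$success$escape), "\n")
  cat("  first-cast success: 1-cast", fmt(x$first_cast_success$one_cast),
      "| n-cast", fmt(x$first_cast_success$n_cast),
      "| pooled", fmt(x$first_cast_success$pooled), "\n")
  cat("  failed first casts rejected:", fmt(x$failed_first$rejected), "\n")
  cat("  successful first casts accepted:",
      fmt(x$successful_first$accepted), "\n")
  invisible(x)
}

# Serialisable form of a summary (drops data.frame payloads to records).
summary_to_list <- function(x) {
  out <- unclass(x)
  out$amplitudes <- if (nrow(x$amplitudes) > 0) x$amplitudes else NULL
  out$heading_angles <- if (NROW(x$heading_angles) > 0) x$heading_angles else NULL
  out
}
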