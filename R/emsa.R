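## Competition-EMSA statistics.
##
## In the competition assay an unlabelled competitor sequence displaces a
## labelled high-affinity RE1 probe from purified REST protein; comparing
## the bound and unbound probe band intensities yields "Fraction Bound"
## (FB), which approaches 0 for a strong competitor (high-affinity RE1)
## and 1 for a non-binder.  Allele comparisons use three independent
## replicate reactions and an unpaired, pooled-variance Student's t test,
## one-sided in the direction of the observed difference, uncorrected for
## multiple testing.

#' Fraction Bound of a gel lane
#'
#' @param bound,unbound nonnegative band intensities (arbitrary
#'   fluorescence units); vectorized.
#' @return `bound / (bound + unbound)`, in \[0, 1\].
#' @export
fraction_bound <- function(bound, unbound) {
  if (any(bound < 0) || any(unbound < 0))
    stop("band intensities must be nonnegative")
  tot <- bound + unbound
  if (any(tot == 0))
    stop("bound + unbound must be positive in every lane")
  bound / tot
}

# One-sided pooled-variance (Student) t-test p-value in the direction of
# the observed mean difference; returns 0.5 at a zero t statistic.
pooled_t_onesided <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / (nx + ny - 2)
  se <- sqrt(sp2 * (1 / nx + 1 / ny))
  if (se == 0) return(if (mean(x) == mean(y)) 0.5 else 0)
  t <- (mean(x) - mean(y)) / se
  stats::pt(-abs(t), df = nx + ny - 2)
}

#' Compare Fraction Bound between Major and Minor alleles
#'
#' @param major_reps,minor_reps numeric vectors of replicate Fraction
#'   Bound values (>= 2 each; the assay design uses 3).
#' @return List of class `AffinityComparison`: `fb_major_mean/sd`,
#'   `fb_minor_mean/sd`, `n_major`, `n_minor`, `delta_fb`
#'   (`fb_minor_mean - fb_major_mean`), `p_value` (one-sided pooled t;
#'   0.5 when the means are equal).
#' @export
compare_alleles <- function(major_reps, minor_reps) {
  if (length(major_reps) < 2L || length(minor_reps) < 2L)
    stop("at least 2 replicates per allele are required")
  if (any(major_reps < 0 | major_reps > 1) ||
      any(minor_reps < 0 | minor_reps > 1))
    stop("Fraction Bound values must lie in [0, 1]")
  structure(list(
    fb_major_mean = mean(major_reps), fb_major_sd = sd(major_reps),
    fb_minor_mean = mean(minor_reps), fb_minor_sd = sd(minor_reps),
    n_major = length(major_reps), n_minor = length(minor_reps),
    delta_fb = mean(minor_reps) - mean(major_reps),
    p_value = pooled_t_onesided(minor_reps, major_reps)),
    class = "AffinityComparison")
}

#' Classify the allelic affinity effect
#'
#' `DOWN`: the minor allele binds REST less strongly (Fraction Bound
#' increases by at least `delta_min` with p < `alpha`); `UP`: the minor
#' allele binds more strongly; otherwise `NO_DIFFERENCE`.
#'
#' @param comp an `AffinityComparison`.
#' @param delta_min minimum |Fraction Bound change| (default 0.1).
#' @param alpha significance level (default 0.05, uncorrected).
#' @return One of `"UP"`, `"DOWN"`, `"NO_DIFFERENCE"`.
#' @export
classify_effect <- function(comp, delta_min = 0.1, alpha = 0.05) {
  if (comp$delta_fb >= delta_min && comp$p_value < alpha) "DOWN"
  else if (comp$delta_fb <= -delta_min && comp$p_value < alpha) "UP"
  else "NO_DIFFERENCE"
}

#' Allele comparison table from raw lane quantifications
#'
#' Groups a lane table (one gel lane per row) by competitor, computes
#' Fraction Bound per lane, compares Major vs Minor replicates, and
#' classifies each competitor's effect.  Control lanes (allele =
#' "control") are ignored here.
#'
#' @param lanes data.frame from [read_emsa_lanes()].
#' @param delta_min,alpha passed to [classify_effect()].
#' @param p_adjust optional multiple-testing correction method for an
#'   extra `p_adj` column (e.g. "BH"); default `"none"` (the screen's
#'   convention is uncorrected p-values).
#' @return data.frame: `competitor_label`, `fb_major_mean`, `fb_minor_mean`,
#'   `delta_fb`, `p_value`, (`p_adj`,) `effect_class`.
#' @export
emsa_comparison_table <- function(lanes, delta_min = 0.1, alpha = 0.05,
                                  p_adjust = "none") {
  lanes$fb <- fraction_bound(lanes$bound, lanes$unbound)
  labs <- unique(lanes$competitor_label[lanes$allele %in% c("major", "minor")])
  rows <- lapply(labs, function(lab) {
    sub <- lanes[lanes$competitor_label == lab, ]
    comp <- compare_alleles(sub$fb[sub$allele == "major"],
                            sub$fb[sub$allele == "minor"])
    data.frame(competitor_label = lab,
               fb_major_mean = comp$fb_major_mean,
               fb_minor_mean = comp$fb_minor_mean,
               delta_fb = comp$delta_fb, p_value = comp$p_value,
               n_major = comp$n_major, n_minor = comp$n_minor,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (p_adjust != "none") out$p_adj <- p.adjust(out$p_value, p_adjust)
  out$effect_class <- vapply(seq_len(nrow(out)), function(i)
    classify_effect(list(delta_fb = out$delta_fb[i],
                         p_value = out$p_value[i]),
                    delta_min = delta_min, alpha = alpha), character(1))
  out
}

#' Positional profile of allelic affinity effects
#'
#' Groups |Fraction Bound change| by the SNP's position within the RE1
#' motif, to show which motif positions are most sensitive to
#' substitution.
#'
#' @param records data.frame with `motif_position` and `delta_fb` columns
#'   (a joined pRE1 catalogue / comparison table).
#' @return data.frame: `motif_position`, `n`, `mean_abs_delta_fb`,
#'   plus a `values` list-column of the per-record |delta FB|.
#' @export
position_effect_profile <- function(records) {
  if (!nrow(records))
    return(data.frame(motif_position = integer(), n = integer(),
                      mean_abs_delta_fb = numeric()))
  adf <- abs(records$delta_fb)
  pos <- sort(unique(records$motif_position))
  out <- data.frame(
    motif_position = pos,
    n = vapply(pos, function(p) sum(records$motif_position == p), integer(1)),
    mean_abs_delta_fb = vapply(pos, function(p)
      mean(adf[records$motif_position == p]), numeric(1)))
  out$values <- lapply(pos, function(p) adf[records$motif_position == p])
  out
}

#' Relative luciferase reporter activity
#'
#' Firefly readings are normalized to the cotransfected Renilla control,
#' then to the same ratio from the empty backbone (no RE1 insert), so 1.0
#' means no repression and values < 1 mean REST-mediated repression.
#'
#' @param firefly,renilla readings from the RE1-carrying construct.
#' @param empty_firefly,empty_renilla readings from the empty backbone.
#' @return `(firefly/renilla) / (empty_firefly/empty_renilla)`.
#' @export
luciferase_relative_activity <- function(firefly, renilla,
                                         empty_firefly, empty_renilla) {
  if (any(c(firefly, renilla, empty_firefly, empty_renilla) <= 0))
    stop("luminescence readings must be positive")
  (firefly / renilla) / (empty_firefly / empty_renilla)
}

#' Compare reporter activity between alleles
#'
#' Two-sided pooled-variance t test between Major- and Minor-allele
#' relative activities, with the direction of the difference and an
#' optional consistency flag against an expected EMSA effect class
#' (a minor allele with increased affinity, class "UP", is expected to
#' repress the reporter more strongly, i.e. lower activity).
#'
#' @param major_activities,minor_activities numeric vectors (>= 2 each).
#' @param expected_class optional EMSA class ("UP"/"DOWN"/"NO_DIFFERENCE").
#' @return List: `p_value` (two-sided; 1 when both groups are degenerate
#'   with equal means), `direction` (sign of mean(minor) - mean(major)),
#'   `mean_major`, `mean_minor`, and `consistent` when `expected_class`
#'   is given.
#' @export
compare_reporter_alleles <- function(major_activities, minor_activities,
                                     expected_class = NULL) {
  if (length(major_activities) < 2L || length(minor_activities) < 2L)
    stop("at least 2 values per group are required")
  p1 <- pooled_t_onesided(minor_activities, major_activities)
  p <- min(1, 2 * p1)
  dir <- sign(mean(minor_activities) - mean(major_activities))
  out <- list(p_value = p, direction = dir,
              mean_major = mean(major_activities),
              mean_minor = mean(minor_activities))
  if (!is.null(expected_class)) {
    out$consistent <- switch(expected_class,
      UP = dir < 0,                  # stronger repression of minor
      DOWN = dir > 0,
      NO_DIFFERENCE = p >= 0.05,
      NA)
  }
  out
}
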