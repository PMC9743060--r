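#' Count activated voxels per atlas region
#'
#' The volume of activation: for each atlas region, the number of
#' nonzero voxels of each sign component of an atlas-space activation
#' map.
#'
#' @param map a `phbold_actmap` whose components are on the atlas grid
#'   (e.g. transferred with [map_to_atlas()] using nearest-neighbour
#'   interpolation), or a list with `positive`/`negative` 3D arrays.
#' @param atlas a `phbold_atlas` on the same grid.
#' @return data.frame with `region`, `name`, `n_pos`, `n_neg`.
#' @export
count_activated <- function(map, atlas) {
  d <- dim(atlas$labels)
  if (!identical(dim(map$positive), d)) {
    stop("activation map and atlas are on different grids")
  }
  lab <- atlas$labels
  inb <- lab > 0
  n <- length(atlas$names)
  count_sign <- function(v) {
    act <- inb & !is.na(v) & v != 0
    tabulate(lab[act], nbins = n)
  }
  data.frame(region = as.integer(names(atlas$names)),
             name = unname(atlas$names),
             n_pos = count_sign(map$positive),
             n_neg = count_sign(map$negative),
             stringsAsFactors = FALSE)
}

#' Kruskal-Wallis comparison of regional counts across groups
#'
#' Rank-based k-group omnibus test on mid-ranks with tie correction,
#' with the p-value from the chi-square approximation on k - 1 degrees
#' of freedom. When every observation is identical the statistic is 0
#' and p is 1.
#'
#' @param x list of numeric vectors, one per group (>= 2 nonempty
#'   groups, total n >= 3).
#' @return list with `H`, `df`, `p`.
#' @export
kruskal_wallis <- function(x) {
  stopifnot(is.list(x), length(x) >= 2)
  n <- lengths(x)
  stopifnot(all(n >= 1), sum(n) >= 3)
  values <- unlist(x, use.names = FALSE)
  if (length(unique(values)) == 1) {
    return(list(H = 0, df = length(x) - 1L, p = 1))
  }
  g <- factor(rep(seq_along(x), n))
  kt <- stats::kruskal.test(values, g)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value)
}

#' Wilcoxon rank-sum post hoc test
#'
#' Two-sided comparison of two groups of per-subject counts: exact
#' enumeration when both samples have at most 8 observations and no
#' ties, otherwise the normal approximation with tie and continuity
#' correction.
#'
#' @param a,b numeric vectors (nonempty).
#' @return two-sided p-value.
#' @export
wilcoxon_ranksum <- function(a, b) {
  stopifnot(length(a) >= 1, length(b) >= 1)
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- length(a) <= 8 && length(b) <= 8 && !ties
  suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = TRUE)$p.value
  )
}

#' Rank-based effect size for a Kruskal-Wallis comparison
#'
#' The default "adjusted" estimator is (H - k + 1) / (n - k), which is 0
#' at the null expectation H = k - 1 and 1 at the maximal H; values are
#' clipped to \[0, 1\]. The "simple" variant H / (n - 1) (the
#' epsilon-squared form) is also available since published tables rarely
#' state which estimator produced their omega-squared column.
#'
#' @param H Kruskal-Wallis statistic.
#' @param n_total total number of observations (> k_groups).
#' @param k_groups number of groups.
#' @param variant "adjusted" or "simple".
#' @return effect size in \[0, 1\].
#' @export
effect_size <- function(H, n_total, k_groups, variant = c("adjusted", "simple")) {
  variant <- match.arg(variant)
  if (n_total <= k_groups) stop("effect size undefined: n_total must exceed k_groups")
  es <- switch(variant,
               adjusted = (H - k_groups + 1) / (n_total - k_groups),
               simple = H / (n_total - 1))
  min(max(es, 0), 1)
}

#' Rank regions and apply the region-list false-detection cutoff
#'
#' Sorts region rows by ascending omnibus p-value and applies the same
#' step-up rule as the voxel filter ([fdr_filter()], one implementation,
#' two call sites) with V equal to the number of regions analyzed. The
#' realized significance cutoff is (i*/V)(q/cV) where i* is the number
#' of retained rows; with 134 regions, 54 retained rows give the .08
#' level and 52 give .077.
#'
#' @param table data.frame with a `p` column (one row per region).
#' @param q,cV filter parameters.
#' @return the table sorted by p with `rank` and `pass` columns and a
#'   `cutoff` attribute (NA when nothing is retained).
#' @export
rank_and_cut <- function(table, q = 0.2, cV = 1) {
  stopifnot(is.data.frame(table), "p" %in% names(table))
  V <- nrow(table)
  out <- table[order(table$p), , drop = FALSE]
  out$rank <- seq_len(V)
  out$pass <- if (V > 0) fdr_filter(out$p, q = q, cV = cV) else logical(0)
  n_pass <- sum(out$pass)
  attr(out, "cutoff") <- if (n_pass > 0) n_pass / V * (q / cV) else NA_real_
  rownames(out) <- NULL
  out
}

#' Classify a regional dose-response profile
#'
#' Labels the shape of the four group medians (vehicle and three
#' ascending doses). Among the three doses: "descending" when medians
#' strictly decrease with dose, "ascending" when they strictly increase,
#' "U-shaped" when the middle dose is strictly smallest with both
#' neighbours larger, "single-dose-max" when a strict maximum exists
#' without those orderings, and "comparable" otherwise (including
#' everything within `tol`). The dose with the largest median is always
#' reported.
#'
#' @param medians numeric length 4: vehicle, low, mid, high dose.
#' @param doses labels for the three dose levels.
#' @param tol medians whose range is <= `tol` are called comparable.
#' @return list with `label` and `max_dose`.
#' @export
classify_profile <- function(medians, doses = c("1.0", "3.3", "10"), tol = 0) {
  stopifnot(length(medians) == 4)
  d <- medians[2:4]
  max_dose <- doses[which.max(d)]
  label <- if (diff(range(d)) <= tol) {
    "comparable"
  } else if (d[1] > d[2] && d[2] > d[3]) {
    "descending"
  } else if (d[1] < d[2] && d[2] < d[3]) {
    "ascending"
  } else if (d[2] < d[1] && d[2] < d[3]) {
    "U-shaped"
  } else if (sum(d == max(d)) == 1) {
    "single-dose-max"
  } else {
    "comparable"
  }
  list(label = label, max_dose = max_dose)
}

#' Regional dose-response tables from per-subject counts
#'
#' Builds the ranked volume-of-activation table for one sign: per
#' region, the group medians, the Kruskal-Wallis omnibus p on the
#' per-subject count vectors, the rank-based effect size, the profile
#' classification, and the region-list step-up cutoff. Post hoc Wilcoxon
#' rank-sum p-values for each dose against vehicle are appended.
#'
#' @param counts data.frame with columns `subject_id`, `group`,
#'   `region`, `name`, and a count column named by `sign` ("n_pos" or
#'   "n_neg"), e.g. rows of [count_activated()] stacked over subjects.
#' @param groups character vector giving the group order: vehicle first,
#'   then ascending doses.
#' @param sign which count column to analyze.
#' @param q,cV region-list filter parameters.
#' @param effect_variant passed to [effect_size()].
#' @param profile_tol passed to [classify_profile()].
#' @return data.frame sorted by p with medians per group, `H`, `p`,
#'   `omega_sq`, post hoc columns `w_<group>`, `profile`, `max_dose`,
#'   `rank`, `pass`; attribute `cutoff`.
#' @export
regional_table <- function(counts, groups = c("vehicle", "mg1", "mg3.3", "mg10"),
                           sign = c("n_pos", "n_neg"), q = 0.2, cV = 1,
                           effect_variant = "adjusted", profile_tol = 0) {
  sign <- match.arg(sign)
  stopifnot(all(groups %in% counts$group), length(groups) == 4)
  regions <- sort(unique(counts$region))
  rows <- lapply(regions, function(r) {
    sub <- counts[counts$region == r, , drop = FALSE]
    by_group <- lapply(groups, function(g) sub[[sign]][sub$group == g])
    kw <- kruskal_wallis(by_group)
    meds <- vapply(by_group, stats::median, numeric(1))
    prof <- classify_profile(meds, tol = profile_tol)
    posthoc <- vapply(2:4, function(i) {
      wilcoxon_ranksum(by_group[[i]], by_group[[1]])
    }, numeric(1))
    out <- data.frame(region = r, name = sub$name[1], stringsAsFactors = FALSE)
    for (i in seq_along(groups)) out[[paste0("median_", groups[i])]] <- meds[i]
    out$H <- kw$H
    out$p <- kw$p
    out$omega_sq <- effect_size(kw$H, sum(lengths(by_group)), length(groups),
                                variant = effect_variant)
    for (i in 2:4) out[[paste0("w_", groups[i])]] <- posthoc[i - 1]
    out$profile <- prof$label
    out$max_dose <- groups[2:4][which.max(meds[2:4])]
    out
  })
  rank_and_cut(do.call(rbind, rows), q = q, cV = cV)
}
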