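## Baseline biomarker candidates, diversity indices, threshold subgroups,
## response probability / responder inclusion score, and ranking.

#' Richness, Shannon index and evenness of a composition
#'
#' Richness \code{S} counts classes above the extinction threshold (1 cell,
#' since continuous ODE states never reach exact zero); the Shannon index
#' is \code{H = -sum p_k log p_k} over surviving classes (nats) and the
#' evenness is \code{J = H / log S} (undefined for S <= 1).
#'
#' @param counts Non-negative class counts (cells).
#' @param extinction_threshold Minimum count for a class to count as
#'   present.
#' @return List with \code{richness}, \code{shannon}, \code{evenness}
#'   (NA when S <= 1).
#' @examples
#' diversity(rep(100, 5))  # H = log(5), J = 1
#' @export
diversity <- function(counts, extinction_threshold = 1) {
  stopifnot(all(counts >= 0))
  alive <- counts[counts >= extinction_threshold]
  S <- length(alive)
  if (S == 0) return(list(richness = 0L, shannon = 0, evenness = NA_real_))
  p <- alive / sum(alive)
  H <- -sum(p * log(p))
  J <- if (S >= 2) H / log(S) else NA_real_
  list(richness = as.integer(S), shannon = H, evenness = J)
}

## candidate registry: each entry computes one per-patient baseline value.
## Tumour/LN quantities are averaged over the patient's metastatic lesions
## and their draining lymph nodes. Densities are cells/mL; ratios are
## dimensionless; NA marks an undefined value (e.g. a 0/0 ratio).
candidate_registry <- function() {
  avg_tum <- function(p, f) {
    les <- baseline_lesions(p)
    les <- setdiff(les, "tumor_primary")
    if (!length(les)) les <- baseline_lesions(p)
    mean(vapply(les, function(tc) f(p$baseline_state, tc, p), numeric(1)))
  }
  avg_ln <- function(p, f) {
    les <- setdiff(baseline_lesions(p), "tumor_primary")
    if (!length(les)) les <- baseline_lesions(p)
    lns <- unique(unname(ln_of_tumor(les)))
    mean(vapply(lns, function(l) f(p$baseline_state, l, p), numeric(1)))
  }
  g <- function(y, comp, sp) unname(y[paste0(comp, ".", sp)])
  tum_counts <- function(y, tc) {
    tcyt <- sum(y[paste0(tc, ".tcyt.", 1:8)])
    c(cancer = sum(y[paste0(tc, ".cancer.", 1:5)]),
      tcyt = tcyt, tex = g(y, tc, "tcyt_exhausted"),
      th = g(y, tc, "th"), treg = g(y, tc, "treg"),
      m1 = g(y, tc, "m1"), m2 = g(y, tc, "m2"), mdsc = g(y, tc, "mdsc"),
      apc = g(y, tc, "apc_immature") + g(y, tc, "apc_mature"))
  }
  tum_vol <- function(y, tc, p)
    max((sum(y[paste0(tc, ".cancer.", 1:5)]) + g(y, tc, "dead")) *
          p$params[["v_cell"]], 1e-6)
  dens <- function(sp) function(p) avg_tum(p, function(y, tc, pp) {
    n <- tum_counts(y, tc)
    n[[sp]] / tum_vol(y, tc, pp)
  })
  ratio <- function(num, den) function(p) avg_tum(p, function(y, tc, pp) {
    n <- tum_counts(y, tc)
    a <- sum(n[num]); b <- sum(n[den])
    if (b <= 0) return(NA_real_)
    a / b
  })

  list(
    density_tcyt_tumor = dens("tcyt"),
    density_th_tumor = dens("th"),
    density_treg_tumor = dens("treg"),
    density_m1_tumor = dens("m1"),
    density_m2_tumor = dens("m2"),
    density_mdsc_tumor = dens("mdsc"),
    density_apc_tumor = dens("apc"),
    ratio_m2_m1 = ratio("m2", "m1"),
    ratio_treg_tcyt = ratio("treg", "tcyt"),
    ratio_supp_act = ratio(c("treg", "m2", "mdsc"), c("tcyt", "th", "m1")),
    frac_til = function(p) avg_tum(p, function(y, tc, pp) {
      n <- tum_counts(y, tc)
      tot <- sum(n[c("cancer", "tcyt", "tex", "th", "treg",
                     "m1", "m2", "mdsc", "apc")])
      if (tot <= 0) return(NA_real_)
      sum(n[c("tcyt", "tex", "th", "treg")]) / tot
    }),
    frac_immune_tumor = function(p) avg_tum(p, function(y, tc, pp) {
      n <- tum_counts(y, tc)
      tot <- sum(n)
      if (tot <= 0) return(NA_real_)
      (tot - n[["cancer"]]) / tot
    }),
    frac_exhausted_tcyt = function(p) avg_tum(p, function(y, tc, pp) {
      n <- tum_counts(y, tc)
      if (n[["tcyt"]] + n[["tex"]] <= 0) return(NA_real_)
      n[["tex"]] / (n[["tcyt"]] + n[["tex"]])
    }),
    pdl1_tumor = function(p) avg_tum(p, function(y, tc, pp)
      g(y, tc, "pdl1")),
    il10_tumor = function(p) avg_tum(p, function(y, tc, pp)
      g(y, tc, "il10")),
    tgfb_tumor = function(p) avg_tum(p, function(y, tc, pp)
      g(y, tc, "tgfb")),
    ifng_tumor = function(p) avg_tum(p, function(y, tc, pp)
      g(y, tc, "ifng")),
    cancer_clone_richness = function(p) avg_tum(p, function(y, tc, pp)
      diversity(y[paste0(tc, ".cancer.", 1:5)])$richness),
    cancer_clone_shannon = function(p) avg_tum(p, function(y, tc, pp)
      diversity(y[paste0(tc, ".cancer.", 1:5)])$shannon),
    cancer_clone_evenness = function(p) avg_tum(p, function(y, tc, pp) {
      e <- diversity(y[paste0(tc, ".cancer.", 1:5)])$evenness
      if (is.na(e)) 0 else e
    }),
    n_neoag_tcell_clones = function(p) {
      # surviving neo-epitope specificities x clonotypes per specificity
      les <- baseline_lesions(p)
      y <- p$baseline_state
      per_spec <- rowSums(vapply(les, function(tc)
        y[paste0(tc, ".tcyt.", 1:8)], numeric(8)))
      diversity(per_spec)$richness * p$params[["n_clonotypes"]]
    },
    tcyt_richness_ln = function(p) avg_ln(p, function(y, l, pp)
      diversity(y[paste0(l, ".tact.", 1:8)])$richness),
    tcyt_shannon_ln = function(p) avg_ln(p, function(y, l, pp)
      diversity(y[paste0(l, ".tact.", 1:8)])$shannon),
    tcyt_evenness_ln = function(p) avg_ln(p, function(y, l, pp) {
      e <- diversity(y[paste0(l, ".tact.", 1:8)])$evenness
      if (is.na(e)) 0 else e
    }),
    density_apc_ln = function(p) avg_ln(p, function(y, l, pp)
      g(y, l, "apc_mature") / pp$params[["v_ln"]] / 1000),
    density_treg_ln = function(p) avg_ln(p, function(y, l, pp)
      g(y, l, "tact_treg") / pp$params[["v_ln"]] / 1000),
    frac_tcyt_t_ln = function(p) avg_ln(p, function(y, l, pp) {
      tc <- sum(y[paste0(l, ".tact.", 1:8)])
      tot <- tc + g(y, l, "tact_th") + g(y, l, "tact_treg")
      if (tot <= 0) return(NA_real_)
      tc / tot
    }),
    frac_tcyt_t_central = function(p) {
      y <- p$baseline_state
      tc <- sum(y[paste0("central.tcyt.", 1:8)])
      tot <- tc + y[["central.th"]] + y[["central.treg"]]
      if (tot <= 0) return(NA_real_)
      tc / tot
    },
    baseline_diameter = function(p) {
      les <- baseline_lesions(p)
      max(lesion_diameters(p$baseline_state, p$params, les))
    },
    sum_baseline_diameter = function(p) {
      les <- baseline_lesions(p)
      sum(lesion_diameters(p$baseline_state, p$params, les))
    },
    n_lesions = function(p) length(baseline_lesions(p))
  )
}

#' Baseline biomarker-candidate table for a cohort
#'
#' Evaluates the candidate registry (densities, ratios, fractions, PD-L1
#' level, cytokines, clonal and T-cell diversity indices, lesion geometry)
#' on every patient's baseline state. Tumour and lymph-node candidates are
#' averages over the patient's metastatic lesions / draining nodes.
#'
#' @param cohort Accepted cohort from [generate_cohort()].
#' @param responder Optional named logical vector of responder labels
#'   (CR/PR/SD); attach later with [responder_labels()] if absent.
#' @return data.frame (class \code{biomarker_table}): one row per patient,
#'   one column per candidate, plus \code{id} and (if given)
#'   \code{responder}. Undefined values are NA and excluded pairwise.
#' @export
extract_candidates <- function(cohort, responder = NULL) {
  reg <- candidate_registry()
  rows <- lapply(cohort, function(p) {
    v <- vapply(reg, function(f) {
      out <- try(f(p), silent = TRUE)
      if (inherits(out, "try-error") || !length(out)) NA_real_
      else as.numeric(out)
    }, numeric(1))
    c(v)
  })
  tab <- as.data.frame(do.call(rbind, rows))
  tab$id <- vapply(cohort, function(p) p$id, character(1))
  if (!is.null(responder)) {
    stopifnot(!any(is.na(responder[tab$id])))
    tab$responder <- unname(responder[tab$id])
  }
  class(tab) <- c("biomarker_table", "data.frame")
  tab
}

candidate_columns <- function(table) {
  setdiff(names(table), c("id", "responder"))
}

#' Threshold-defined patient subgroups for one candidate
#'
#' Chooses uniformly spaced cutoffs spanning the observed range of the
#' candidate (interior cutoffs, so no subgroup is degenerate by
#' construction) and forms, for each cutoff, an "above" (value >= cutoff)
#' and a "below" (value < cutoff) subgroup. Subgroups smaller than
#' \code{min_size} are discarded; subgroups may overlap.
#'
#' @param values Named numeric vector (names = patient ids); NAs excluded.
#' @param n_thresholds Number of cutoffs (default 8).
#' @param min_size Minimum subgroup size (default 20).
#' @return List of subgroups: \code{direction}, \code{threshold},
#'   \code{members} (ids). Empty list for a constant candidate.
#' @export
make_subgroups <- function(values, n_thresholds = 8, min_size = 20) {
  v <- values[!is.na(values)]
  if (length(v) < min_size) return(list())
  rng <- range(v)
  if (rng[1] == rng[2]) return(list())
  cuts <- seq(rng[1], rng[2],
              length.out = n_thresholds + 2)[seq_len(n_thresholds) + 1]
  out <- list()
  for (ct in cuts) {
    for (dir in c("above", "below")) {
      members <- names(v)[if (dir == "above") v >= ct else v < ct]
      if (length(members) >= min_size)
        out[[length(out) + 1]] <- list(direction = dir, threshold = ct,
                                       members = members)
    }
  }
  out
}

#' Response probability of a subgroup
#'
#' Fraction of responders among the patients of the subgroup.
#'
#' @param members Patient ids in the subgroup (non-empty).
#' @param responder Named logical vector over the cohort.
#' @return Value in \[0, 1\].
#' @export
response_probability <- function(members, responder) {
  if (!length(members)) stop("empty subgroup")
  mean(responder[members])
}

#' Responder inclusion score of a subgroup
#'
#' The fraction of all cohort responders captured by the subgroup minus
#' the fraction of all cohort nonresponders captured; ranges over
#' \[-1, 1\], equals 0 for the full cohort and 1 for a subgroup holding
#' exactly the responders.
#'
#' @param members Patient ids in the subgroup.
#' @param responder Named logical vector over the entire cohort.
#' @return Value in \[-1, 1\].
#' @export
ris <- function(members, responder) {
  n_resp <- sum(responder)
  n_nonresp <- sum(!responder)
  if (n_resp == 0 || n_nonresp == 0)
    stop("RIS undefined: cohort must contain responders and nonresponders")
  sum(responder[members]) / n_resp - sum(!responder[members]) / n_nonresp
}

subgroup_metric <- function(members, responder, metric) {
  if (metric == "rp") response_probability(members, responder)
  else ris(members, responder)
}

## percentile bootstrap of a fixed threshold rule: patients are resampled,
## membership recomputed by the frozen (direction, threshold) rule
boot_subgroup_ci <- function(values, responder, direction, threshold,
                             metric, n_boot, seed) {
  set.seed(seed)
  ids <- names(values)[!is.na(values)]
  n <- length(ids)
  stat <- vapply(seq_len(n_boot), function(b) {
    take <- sample(ids, n, replace = TRUE)
    v <- values[take]; r <- responder[take]
    m <- if (direction == "above") v >= threshold else v < threshold
    if (!any(m)) return(NA_real_)
    if (metric == "rp") mean(r[m])
    else {
      if (!any(r) || all(r)) return(NA_real_)
      sum(r[m]) / sum(r) - sum(!r & m) / sum(!r)
    }
  }, numeric(1))
  stats::quantile(stat, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
}

best_subgroup <- function(values, responder, metric, n_thresholds,
                          min_size) {
  sgs <- make_subgroups(values, n_thresholds, min_size)
  if (!length(sgs)) return(NULL)
  scores <- vapply(sgs, function(s)
    subgroup_metric(s$members, responder, metric), numeric(1))
  sizes <- vapply(sgs, function(s) length(s$members), numeric(1))
  ord <- order(-scores, -sizes)
  best <- sgs[[ord[1]]]
  best$value <- scores[ord[1]]
  best$n <- as.integer(sizes[ord[1]])
  best
}

#' Rank single biomarker candidates
#'
#' For every candidate, enumerates the threshold subgroups, scores each by
#' the chosen metric (response probability \code{"rp"} or responder
#' inclusion score \code{"ris"}), keeps the best subgroup and ranks the
#' candidates by that best value (ties: larger subgroup, then name).
#' Percentile-bootstrap confidence intervals resample patients with the
#' threshold rule held fixed.
#'
#' @param table A [extract_candidates()] table with a \code{responder}
#'   column.
#' @param metric \code{"rp"} or \code{"ris"}.
#' @param n_thresholds,min_size Subgroup construction settings.
#' @param n_boot,seed Bootstrap settings (\code{n_boot = 0} skips CIs).
#' @return data.frame sorted by decreasing best value: candidate,
#'   direction, threshold, n, value, ci_low, ci_high.
#' @export
rank_candidates <- function(table, metric = c("rp", "ris"),
                            n_thresholds = 8, min_size = 20,
                            n_boot = 200, seed = 1L) {
  metric <- match.arg(metric)
  stopifnot("responder" %in% names(table))
  responder <- stats::setNames(table$responder, table$id)
  rows <- list()
  for (cand in candidate_columns(table)) {
    values <- stats::setNames(table[[cand]], table$id)
    best <- best_subgroup(values, responder, metric, n_thresholds, min_size)
    if (is.null(best)) next
    ci <- c(NA_real_, NA_real_)
    if (n_boot > 0)
      ci <- boot_subgroup_ci(values, responder, best$direction,
                             best$threshold, metric, n_boot, seed)
    rows[[cand]] <- data.frame(
      candidate = cand, direction = best$direction,
      threshold = best$threshold, n = best$n, value = best$value,
      ci_low = ci[1], ci_high = ci[2], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(out)
  out <- out[order(-out$value, -out$n, out$candidate), ]
  rownames(out) <- NULL
  out
}

#' Rank pairs of biomarker candidates
#'
#' A pair subgroup is the intersection of one thresholded condition per
#' candidate (both directions, all cutoffs: up to 256 combinations per
#' pair before the size filter). Pairs are ranked by the best subgroup
#' value; the signed percent change versus the better of the two single
#' candidates is reported (a pair is not guaranteed to beat its parts;
#' conversely, opposite-direction conjunctions form bands, so even a pair
#' of identical candidates can beat its single-threshold parts).
#'
#' @inheritParams rank_candidates
#' @param candidates Optional subset of candidate columns to pair.
#' @return data.frame sorted by decreasing best value: candidate_1/2,
#'   directions, thresholds, n, value, pct_change_vs_best_single,
#'   ci_low, ci_high.
#' @export
rank_pairs <- function(table, metric = c("rp", "ris"), n_thresholds = 8,
                       min_size = 20, n_boot = 0, seed = 1L,
                       candidates = NULL) {
  metric <- match.arg(metric)
  stopifnot("responder" %in% names(table))
  responder <- stats::setNames(table$responder, table$id)
  cands <- candidates %||% candidate_columns(table)
  stopifnot(length(cands) >= 2)
  singles <- rank_candidates(table, metric, n_thresholds, min_size,
                             n_boot = 0)
  rows <- list()
  for (i in seq_len(length(cands) - 1)) for (j in (i + 1):length(cands)) {
    c1 <- cands[i]; c2 <- cands[j]
    v1 <- stats::setNames(table[[c1]], table$id)
    v2 <- stats::setNames(table[[c2]], table$id)
    s1 <- make_subgroups(v1, n_thresholds, 1L)
    s2 <- make_subgroups(v2, n_thresholds, 1L)
    best <- NULL
    for (a in s1) for (b in s2) {
      members <- intersect(a$members, b$members)
      if (length(members) < min_size) next
      val <- subgroup_metric(members, responder, metric)
      if (is.null(best) || val > best$value ||
          (val == best$value && length(members) > best$n)) {
        best <- list(value = val, n = length(members),
                     dir1 = a$direction, thr1 = a$threshold,
                     dir2 = b$direction, thr2 = b$threshold)
      }
    }
    if (is.null(best)) next
    ref <- suppressWarnings(
      max(singles$value[singles$candidate %in% c(c1, c2)]))
    pct <- if (is.finite(ref) && ref != 0)
      100 * (best$value - ref) / abs(ref) else NA_real_
    rows[[paste(c1, c2, sep = "|")]] <- data.frame(
      candidate_1 = c1, candidate_2 = c2,
      direction_1 = best$dir1, threshold_1 = best$thr1,
      direction_2 = best$dir2, threshold_2 = best$thr2,
      n = best$n, value = best$value,
      pct_change_vs_best_single = pct, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(out)
  out <- out[order(-out$value, -out$n, out$candidate_1, out$candidate_2), ]
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
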