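#' Screening thresholds
#'
#' The decision rules of the essentiality analysis. On consensus models a
#' knockout is essential when the cancer growth ratio is below
#' `cancer_ratio_max` (strict) while the control ATP-maintenance ratio stays
#' at or above `healthy_ratio_min` (inclusive). On sample-specific models
#' the same per-model conditions must hold in at least
#' `cancer_sample_fraction_min` of the screenable cancer models (inclusive)
#' while control models lose their objective (ratio below
#' `healthy_ratio_min`) in at most `healthy_sample_fraction_max` of the
#' screenable control models (inclusive).
#'
#' @param cancer_ratio_max Cancer growth-ratio cutoff; default 0.5.
#' @param healthy_ratio_min Control protection cutoff; default 0.9.
#' @param cancer_sample_fraction_min Minimal fraction of affected cancer
#'   sample models; default 0.5.
#' @param healthy_sample_fraction_max Maximal tolerated fraction of harmed
#'   control sample models; default 0.1.
#' @param consensus_activity_fraction Activity fraction for consensus model
#'   construction; default 0.9.
#' @return An object of class `thresholds`.
#' @export
thresholds <- function(cancer_ratio_max = 0.5, healthy_ratio_min = 0.9,
                       cancer_sample_fraction_min = 0.5,
                       healthy_sample_fraction_max = 0.1,
                       consensus_activity_fraction = 0.9) {
  th <- list(cancer_ratio_max = cancer_ratio_max,
             healthy_ratio_min = healthy_ratio_min,
             cancer_sample_fraction_min = cancer_sample_fraction_min,
             healthy_sample_fraction_max = healthy_sample_fraction_max,
             consensus_activity_fraction = consensus_activity_fraction)
  for (nm in names(th)) {
    v <- th[[nm]]
    if (!is.numeric(v) || length(v) != 1L || v < 0 || v > 1) {
      stop(nm, " must be a proportion in [0, 1]", call. = FALSE)
    }
  }
  structure(th, class = "thresholds")
}

#' Essentiality call on consensus models
#'
#' Essential iff the cancer growth ratio is strictly below
#' `cancer_ratio_max` and the control ratio is at or above
#' `healthy_ratio_min`. A missing control ratio defaults to not essential
#' (fail-safe); set `missing_healthy = "pass"` to call without a safety arm.
#'
#' @param cancer_ratio,healthy_ratio Growth ratios from the consensus
#'   cancer and control models (`NA` allowed for the control).
#' @param th A [thresholds()] object.
#' @param missing_healthy `"fail"` (default) or `"pass"`.
#' @return Logical scalar.
#' @export
call_essential_consensus <- function(cancer_ratio, healthy_ratio,
                                     th = thresholds(),
                                     missing_healthy = c("fail", "pass")) {
  missing_healthy <- match.arg(missing_healthy)
  if (is.na(cancer_ratio)) return(FALSE)
  hits_cancer <- cancer_ratio < th$cancer_ratio_max
  spares_healthy <- if (is.na(healthy_ratio)) missing_healthy == "pass"
    else healthy_ratio >= th$healthy_ratio_min
  hits_cancer && spares_healthy
}

#' Essentiality call on sample-specific models
#'
#' Computes the fraction of screenable cancer models in which the knockout
#' pushes the ratio below `cancer_ratio_max` (the efficacy fraction) and the
#' fraction of screenable control models in which the ratio drops below
#' `healthy_ratio_min` (the harm fraction). Essential iff efficacy is at
#' least `cancer_sample_fraction_min` and harm at most
#' `healthy_sample_fraction_max`. With zero screenable models in either arm
#' the call is undefined (`NA`).
#'
#' @param cancer_ratios,healthy_ratios Numeric vectors of per-sample growth
#'   ratios (`NA` entries mark unscreenable models and are dropped).
#' @param th A [thresholds()] object.
#' @return List with `essential` (logical or `NA`), `cancer_efficacy`,
#'   `control_harm`, `n_cancer`, `n_control`.
#' @export
call_essential_samples <- function(cancer_ratios, healthy_ratios,
                                   th = thresholds()) {
  ca <- cancer_ratios[!is.na(cancer_ratios)]
  he <- healthy_ratios[!is.na(healthy_ratios)]
  eff <- if (length(ca)) mean(ca < th$cancer_ratio_max) else NA_real_
  harm <- if (length(he)) mean(he < th$healthy_ratio_min) else NA_real_
  essential <- if (length(ca) == 0L || length(he) == 0L) NA
    else eff >= th$cancer_sample_fraction_min &&
         harm <= th$healthy_sample_fraction_max
  list(essential = essential, cancer_efficacy = eff, control_harm = harm,
       n_cancer = length(ca), n_control = length(he))
}

#' Drug essentiality score
#'
#' The fraction of screenable sample-specific models in which the drug
#' pushed the condition's objective ratio below its threshold
#' (`cancer_ratio_max` for cancer models on biomass, `healthy_ratio_min`
#' for control models on ATP maintenance). A score of 1 means the drug
#' shuts down its objective in 100 percent of the samples.
#'
#' @param ratios Per-sample growth ratios; `NA` entries are dropped.
#' @param th A [thresholds()] object.
#' @param condition `"cancer"` or `"control"` -- selects the threshold.
#' @return A proportion in `[0, 1]`, or `NA` if no screenable samples.
#' @export
drug_essentiality_score <- function(ratios, th = thresholds(),
                                    condition = c("cancer", "control")) {
  condition <- match.arg(condition)
  cutoff <- if (condition == "cancer") th$cancer_ratio_max
    else th$healthy_ratio_min
  r <- ratios[!is.na(ratios)]
  if (length(r) == 0L) return(NA_real_)
  mean(r < cutoff)
}

#' Number needed to treat
#'
#' The estimated number of patients to treat before seeing one responder:
#' the ceiling of the reciprocal efficacy fraction. Undefined (`NA`) for a
#' score of 0.
#'
#' @param score Efficacy fraction in `[0, 1]`.
#' @return Integer count (>= 1) or `NA`.
#' @export
nnt_estimate <- function(score) {
  stopifnot(is.numeric(score), length(score) == 1L)
  if (is.na(score)) return(NA_integer_)
  stopifnot(score >= 0, score <= 1 + 1e-12)
  if (score == 0) return(NA_integer_)
  as.integer(ceiling(1 / score))
}

#' Hypergeometric enrichment of annotated drugs among predictions
#'
#' One-sided over-representation test: the probability of drawing at least
#' `k` annotated drugs when `n` predictions are drawn from a universe of `N`
#' drugs of which `K` are annotated, i.e. the upper hypergeometric tail.
#'
#' @param predicted Character vector of predicted drug ids (must be a subset
#'   of `universe`).
#' @param annotated Character vector of annotated (e.g. known anticancer)
#'   drug ids.
#' @param universe Character vector: all screened drugs.
#' @return List with `k`, `n`, `K`, `N` and `p_value`.
#' @export
enrichment_score <- function(predicted, annotated, universe) {
  bad <- setdiff(predicted, universe)
  if (length(bad)) {
    stop("predicted drug(s) outside the universe: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  annotated <- intersect(annotated, universe)
  k <- length(intersect(predicted, annotated))
  n <- length(predicted)
  K <- length(annotated)
  N <- length(universe)
  p <- if (n == 0L) 1 else stats::phyper(k - 1, K, N - K, n,
                                         lower.tail = FALSE)
  list(k = k, n = n, K = K, N = N, p_value = p)
}

#' Intersect per-dataset candidate drug sets
#'
#' @param per_dataset Named list of character vectors (dataset -> predicted
#'   drug ids).
#' @return List with `shared` (intersection across all datasets) and
#'   `membership`, a logical drug x dataset matrix of Venn-style counts.
#' @export
intersect_candidates <- function(per_dataset) {
  stopifnot(is.list(per_dataset), length(per_dataset) >= 1L)
  shared <- Reduce(intersect, per_dataset)
  all_drugs <- sort(unique(unlist(per_dataset)))
  membership <- vapply(per_dataset, function(s) all_drugs %in% s,
                       logical(length(all_drugs)))
  if (length(all_drugs) == 1L) {
    membership <- matrix(membership, nrow = 1,
                         dimnames = list(all_drugs, names(per_dataset)))
  } else if (length(all_drugs) == 0L) {
    membership <- matrix(logical(), 0, length(per_dataset),
                         dimnames = list(NULL, names(per_dataset)))
  } else {
    rownames(membership) <- all_drugs
  }
  list(shared = sort(shared), membership = membership)
}

#' Summarize a deletion screen into a per-entity report
#'
#' Combines sample-level outcomes (and, when given, consensus-model
#' outcomes) into one row per screened entity: efficacy and harm fractions,
#' the sample-level and consensus essentiality calls, the drug essentiality
#' score and the NNT estimate.
#'
#' @param sample_outcomes Outcome table from [screen_dataset()] over
#'   sample-specific contexts (cancer and control arms together).
#' @param consensus_outcomes Optional outcome table over consensus contexts.
#' @param th A [thresholds()] object.
#' @return Data frame, one row per entity, sorted by descending efficacy;
#'   class `screen_report`.
#' @export
screen_report <- function(sample_outcomes, consensus_outcomes = NULL,
                          th = thresholds()) {
  stopifnot(is.data.frame(sample_outcomes))
  ents <- unique(sample_outcomes[c("entity_id", "entity_kind")])
  cons_ratio <- function(tab, ent, cond) {
    if (is.null(tab)) return(NA_real_)
    r <- tab$ratio[tab$entity_id == ent & tab$condition == cond &
                     tab$screenable]
    if (length(r)) r[1] else NA_real_
  }
  rows <- lapply(seq_len(nrow(ents)), function(i) {
    ent <- ents$entity_id[i]
    sub <- sample_outcomes[sample_outcomes$entity_id == ent, , drop = FALSE]
    ca <- sub$ratio[sub$condition == "cancer"]
    he <- sub$ratio[sub$condition == "control"]
    s <- call_essential_samples(ca, he, th)
    cc <- cons_ratio(consensus_outcomes, ent, "cancer")
    ch <- cons_ratio(consensus_outcomes, ent, "control")
    score <- drug_essentiality_score(ca, th, "cancer")
    data.frame(entity_id = ent, entity_kind = ents$entity_kind[i],
               consensus_cancer_ratio = cc, consensus_healthy_ratio = ch,
               consensus_essential = if (is.null(consensus_outcomes)) NA
                 else call_essential_consensus(cc, ch, th),
               cancer_efficacy = s$cancer_efficacy,
               control_harm = s$control_harm,
               sample_essential = s$essential,
               n_cancer = s$n_cancer, n_control = s$n_control,
               score = score, nnt = nnt_estimate(score),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$cancer_efficacy, out$entity_id), ]
  rownames(out) <- NULL
  class(out) <- c("screen_report", "data.frame")
  out
}

#' @export
print.screen_report <- function(x, ...) {
  cat(sprintf("<screen_report> %d entities (%d genes, %d drugs)\n",
              nrow(x), sum(x$entity_kind == "gene"),
              sum(x$entity_kind == "drug")))
  NextMethod()
}

#' @export
summary.screen_report <- function(object, ...) {
  ess <- object$entity_id[!is.na(object$sample_essential) &
                            object$sample_essential]
  cat(sprintf("Essential by the sample-level rule: %d of %d entities\n",
              length(ess), nrow(object)))
  if (length(ess)) cat("  ", paste(ess, collapse = ", "), "\n")
  invisible(object)
}
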