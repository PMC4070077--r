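#' Run the planted-module benchmark for one replicate
#'
#' The package's end-to-end study on synthetic data: generate a
#' multi-network benchmark with known per-network informativeness
#' ([generate_fixture()]), pre-process each network (linear rescaling;
#' the generator's weight jitter carries no evidence, so no threshold
#' filtering is applied), then evaluate a prioritizer by node-wise
#' cross-validation on
#'
#' * each single network,
#' * each unweighted integration (UA, PUA, MAX, drastic and soft MIN),
#' * the class-averaged weighted integration WA, with gamma weights
#'   re-estimated inside each training split by internal
#'   cross-validation.
#'
#' @param seed Integer seed driving the fixture, the fold assignment and
#'   the internal weight estimation.
#' @param spec A [fixture_spec()]; defaults to the standard benchmark
#'   conditions (500 genes, 20 diseases, three networks with
#'   informativeness 0.9 / 0.5 / 0.0) at this `seed`.
#' @param method,params Prioritizer specification as in [make_scorer()];
#'   default: S_AV on a 3-step random-walk kernel with a = 2.
#' @param integrations Unweighted operators to evaluate.
#' @param weighted Also run the WA weighted integration?
#' @param folds External fold count.
#' @param internal_f Internal fold count for gamma estimation.
#' @param recall_levels Recall grid for precision-at-recall.
#' @return List with elements `truth` (planted parameters), `single`
#'   (named list of `evaluation_report`s per network), `integrated`
#'   (per operator), `wa` (report or `NULL`), `gamma` (named vector of
#'   WA weights averaged over external folds, or `NULL`) and
#'   `mean_auc` (named vector of mean AUCs across diseases for every
#'   configuration).
#' @examples
#' \donttest{
#' bench <- planted_benchmark(seed = 1,
#'   spec = fixture_spec(n_genes = 150, n_diseases = 5, seed = 1))
#' round(bench$mean_auc, 3)
#' }
#' @export
planted_benchmark <- function(seed = 1L, spec = fixture_spec(seed = seed),
                              method = "sav", params = list(a = 2, q = 3),
                              integrations = c("ua", "pua", "max",
                                               "min-drastic", "min-soft"),
                              weighted = TRUE, folds = 5L, internal_f = 5L,
                              recall_levels = seq(0.1, 1, by = 0.1)) {
  fx <- generate_fixture(spec)
  universe <- attr(fx$networks, "universe")
  col <- network_collection(
    lapply(fx$networks, preprocess_network, threshold = NA),
    universe = universe)
  set.seed(seed)
  plan <- cv_folds(universe, f = folds)

  single <- lapply(names(col), function(nm) {
    scorer <- make_scorer(method, col[[nm]], params)
    cross_validate(scorer, fx$sets, plan, recall_levels)
  })
  names(single) <- names(col)

  integrated <- lapply(integrations, function(m) {
    scorer <- make_scorer(method, integrate_networks(col, m), params)
    cross_validate(scorer, fx$sets, plan, recall_levels)
  })
  names(integrated) <- integrations

  wa <- NULL
  gamma <- NULL
  if (weighted) {
    wa <- cross_validate_weighted(col, fx$sets, method = method,
                                  params = params, integration = "wa",
                                  plan = plan, internal_f = internal_f,
                                  seed = seed + 1L,
                                  recall_levels = recall_levels)
    gmat <- vapply(attr(wa, "gamma"), function(g) g$gamma,
                   numeric(length(col)))
    gamma <- rowMeans(gmat)
  }

  mean_auc <- c(
    vapply(single, function(r) mean(r$auc), 0),
    vapply(integrated, function(r) mean(r$auc), 0),
    if (weighted) c(wa = mean(wa$auc)))
  list(truth = fx$truth, sets = fx$sets, single = single,
       integrated = integrated, wa = wa, gamma = gamma,
       mean_auc = mean_auc)
}
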