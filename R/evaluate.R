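#' Ranking AUC (Mann-Whitney statistic)
#'
#' The probability that a uniformly chosen positive gene outranks a
#' uniformly chosen negative one, with ties credited 1/2. Equivalent to
#' the area under the ROC curve of the ranking, and invariant under any
#' strictly monotone transform of the scores.
#'
#' @param scores Named numeric vector of gene scores.
#' @param positives Character vector of positive genes (must appear in
#'   `scores`).
#' @return The AUC in \[0, 1\]; `NA` if either class is empty.
#' @export
ranking_auc <- function(scores, positives) {
  if (is.null(names(scores))) stop("scores must be named by gene")
  is_pos <- names(scores) %in% positives
  np <- sum(is_pos)
  nn <- length(scores) - np
  if (np == 0L || nn == 0L) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[is_pos]) - np * (np + 1) / 2) / (np * nn)
}

#' Precision at fixed recall levels
#'
#' Ranks genes by descending score (ties broken lexicographically by
#' gene identifier) and, for each requested recall level r, reports the
#' precision at the smallest cutoff whose recall reaches r. Useful when
#' positives are few and the AUC alone hides how clean the top of the
#' ranking is.
#'
#' @param scores Named numeric vector of gene scores.
#' @param positives Character vector of positive genes.
#' @param recall_levels Numeric vector of recall levels in (0, 1].
#' @return Named numeric vector of precisions, one per recall level.
#' @export
precision_at_recall <- function(scores, positives,
                                recall_levels = seq(0.1, 1, by = 0.1)) {
  if (is.null(names(scores))) stop("scores must be named by gene")
  stopifnot(all(recall_levels > 0), all(recall_levels <= 1))
  ord <- order(-scores, names(scores), method = "radix")
  lab <- as.integer(names(scores)[ord] %in% positives)
  np <- sum(lab)
  if (np == 0L) {
    return(stats::setNames(rep(NA_real_, length(recall_levels)),
                           paste0("P@", recall_levels)))
  }
  cum_tp <- cumsum(lab)
  prec <- cum_tp / seq_along(lab)
  rec <- cum_tp / np
  out <- vapply(recall_levels, function(r) {
    prec[which(rec >= r - 1e-12)[1L]]
  }, 0)
  stats::setNames(out, paste0("P@", recall_levels))
}

#' Node-wise cross-validation folds
#'
#' Randomly partitions the genes of a universe into f disjoint folds.
#' By default the partition is a plain uniform random split; with
#' `stratify` a set of positives can be spread across folds so that,
#' where possible, every fold holds at least one of them.
#'
#' @param universe A [gene_universe()].
#' @param f Number of folds (>= 2).
#' @param seed Optional integer seed for reproducibility.
#' @param stratify Optional character vector of genes to spread evenly
#'   across folds.
#' @return An object of class `cv_plan`: list with `folds` (list of f
#'   character vectors), `f` and `seed`.
#' @export
cv_folds <- function(universe, f = 5L, seed = NULL, stratify = NULL) {
  if (!inherits(universe, "gene_universe")) universe <- gene_universe(universe)
  stopifnot(f >= 2L, f <= length(universe))
  if (!is.null(seed)) set.seed(seed)
  genes <- unclass(universe)
  assign_round_robin <- function(g) {
    g <- sample(g)
    split(g, rep_len(seq_len(f), length(g)))
  }
  if (is.null(stratify)) {
    folds <- assign_round_robin(genes)
  } else {
    pos <- intersect(genes, stratify)
    neg <- setdiff(genes, pos)
    fp <- assign_round_robin(pos)
    fn <- assign_round_robin(neg)
    folds <- lapply(seq_len(f), function(i) {
      c(if (i <= length(fp)) fp[[i]], if (i <= length(fn)) fn[[i]])
    })
  }
  folds <- lapply(folds, as.character)
  names(folds) <- paste0("fold", seq_len(f))
  structure(list(folds = folds, f = as.integer(f), seed = seed,
                 universe = universe),
            class = "cv_plan")
}

#' @export
print.cv_plan <- function(x, ...) {
  cat("<cv_plan> ", x$f, " folds over ", length(x$universe), " genes\n",
      sep = "")
  invisible(x)
}

# Scores every gene once as a test gene: for each fold, train seeds are
# the positives outside the fold, and the fold genes' scores are kept.
cv_scores_one <- function(scorer, positives, plan) {
  universe <- attr(scorer, "universe")
  out <- stats::setNames(rep(NA_real_, length(universe)), unclass(universe))
  for (fold in plan$folds) {
    seeds <- setdiff(positives, fold)
    if (length(seeds) == 0L) {
      warning("a fold contains every positive gene; its test scores are 0")
      out[fold] <- 0
    } else {
      s <- scorer(seeds)
      out[fold] <- s[fold]
    }
  }
  out
}

#' Cross-validated evaluation of a prioritizer
#'
#' Runs the node-wise k-fold protocol for every disease in `sets`: the
#' labels of the test fold are removed, the remaining positives act as
#' training seeds, all genes are scored, and the scores of the test
#' fold are retained. Once every gene has been scored as a test gene,
#' the assembled ranking is evaluated against the true labels with the
#' AUC and precision at fixed recall levels.
#'
#' @param scorer A scorer from [make_scorer()] (or any function
#'   `f(seeds)` with a `universe` attribute).
#' @param sets A [gene_set_collection()] over the scorer's universe.
#' @param plan A [cv_folds()] plan (default: 5 folds, fresh random
#'   partition).
#' @param recall_levels Recall grid for [precision_at_recall()].
#' @return An object of class `evaluation_report`: a `data.frame` with
#'   one row per disease (`disease`, `n_pos`, `auc`, `P@...` columns)
#'   and the matrix of cross-validated scores (genes x diseases) in
#'   attribute `"scores"`.
#' @export
cross_validate <- function(scorer, sets, plan = NULL,
                           recall_levels = seq(0.1, 1, by = 0.1)) {
  stopifnot(inherits(sets, "gene_set_collection"))
  universe <- attr(scorer, "universe")
  if (is.null(universe)) stop("scorer lacks a universe attribute")
  if (is.null(plan)) plan <- cv_folds(universe, f = 5L)
  stopifnot(inherits(plan, "cv_plan"))
  if (!setequal(unlist(plan$folds), unclass(universe))) {
    stop("the CV plan does not partition the scorer's universe")
  }
  score_mat <- matrix(NA_real_, nrow = length(universe), ncol = length(sets),
                      dimnames = list(unclass(universe), names(sets)))
  rows <- vector("list", length(sets))
  for (i in seq_along(sets)) {
    pos <- sets[[i]]
    s <- cv_scores_one(scorer, pos, plan)
    score_mat[, i] <- s
    rows[[i]] <- c(auc = ranking_auc(s, pos),
                   precision_at_recall(s, pos, recall_levels))
  }
  perf <- do.call(rbind, rows)
  report <- data.frame(disease = names(sets), n_pos = lengths(sets),
                       perf, check.names = FALSE, row.names = NULL,
                       stringsAsFactors = FALSE)
  structure(report, scores = score_mat, plan = plan,
            class = c("evaluation_report", "data.frame"))
}

#' Internal estimation of network reliability weights
#'
#' Estimates, for each member network and each disease, the AUC a
#' prioritizer attains on that network alone, using only the genes in
#' `train_genes` — an internal cross-validation (or exact leave-one-out)
#' nested inside the training split of the outer protocol, so the
#' resulting gamma weights never see test-fold labels. The AUC table is
#' then turned into weights with [compute_gamma()].
#'
#' @param col A [network_collection()].
#' @param sets A [gene_set_collection()].
#' @param method,params Prioritizer specification as in [make_scorer()].
#' @param train_genes Genes visible to the estimation (default: the
#'   whole universe). Positives outside this set are ignored, and only
#'   these genes are scored and ranked internally.
#' @param internal_f Number of internal folds, or `"loo"` for exact
#'   leave-one-out over the training genes.
#' @param transform,b Passed to [compute_gamma()].
#' @param seed Optional seed for the internal fold assignment.
#' @return A `gamma_weights` object (networks as columns, diseases as
#'   rows); the internal AUC table is its `metrics` field. Diseases with
#'   fewer than 2 training positives get uniform weights.
#' @export
estimate_internal_weights <- function(col, sets, method = "sav",
                                      params = list(), train_genes = NULL,
                                      internal_f = 5L,
                                      transform = "linear", b = 0.99,
                                      seed = NULL) {
  stopifnot(inherits(col, "network_collection"),
            inherits(sets, "gene_set_collection"))
  universe <- attr(col, "universe")
  if (is.null(train_genes)) train_genes <- unclass(universe)
  train_genes <- intersect(unclass(universe), train_genes)
  f <- if (identical(internal_f, "loo")) length(train_genes)
       else as.integer(internal_f)
  sub_universe <- gene_universe(train_genes)
  plan <- cv_folds(sub_universe, f = f, seed = seed)
  metrics <- matrix(NA_real_, nrow = length(sets), ncol = length(col),
                    dimnames = list(names(sets), names(col)))
  for (d in seq_along(col)) {
    # restrict the network to the training genes so no test-fold
    # structure or label can influence the estimate
    sub_net <- subset_network(col[[d]], train_genes)
    scorer <- make_scorer(method, sub_net, params)
    for (k in seq_along(sets)) {
      pos <- intersect(sets[[k]], train_genes)
      if (length(pos) < 2L || length(pos) >= length(train_genes)) next
      s <- cv_scores_one(scorer, pos, plan)
      metrics[k, d] <- ranking_auc(s, pos)
    }
  }
  # diseases that could not be estimated contribute uniform weights
  bad <- apply(metrics, 1L, function(m) anyNA(m))
  metrics[bad, ] <- 0.5
  compute_gamma(metrics, transform = transform, b = b)
}

#' Cross-validated evaluation with weighted integration
#'
#' The full weighted-integration protocol: for each external fold, the
#' gamma weights are re-estimated by internal cross-validation on the
#' training genes only ([estimate_internal_weights()]), the member
#' networks are fused with those weights (WA: one network for all
#' diseases; WAP: one per disease), a fresh scorer is built on the
#' integrated network, and the test-fold genes are scored with training
#' seeds. AUC and precision at recall are computed once every gene has
#' been scored as a test gene.
#'
#' @param col A [network_collection()] of pre-processed networks.
#' @param sets A [gene_set_collection()].
#' @param method,params Prioritizer specification as in [make_scorer()].
#' @param integration `"wa"` or `"wap"`.
#' @param plan External [cv_folds()] plan (default 5 folds).
#' @param internal_f,transform,b,seed Passed to
#'   [estimate_internal_weights()].
#' @param recall_levels Recall grid.
#' @return An `evaluation_report` (as in [cross_validate()]) with the
#'   per-fold gamma weights in attribute `"gamma"`.
#' @export
cross_validate_weighted <- function(col, sets, method = "sav",
                                    params = list(),
                                    integration = c("wa", "wap"),
                                    plan = NULL, internal_f = 5L,
                                    transform = "linear", b = 0.99,
                                    seed = NULL,
                                    recall_levels = seq(0.1, 1, by = 0.1)) {
  integration <- match.arg(integration)
  stopifnot(inherits(col, "network_collection"),
            inherits(sets, "gene_set_collection"))
  universe <- attr(col, "universe")
  if (is.null(plan)) plan <- cv_folds(universe, f = 5L, seed = seed)
  score_mat <- matrix(NA_real_, nrow = length(universe), ncol = length(sets),
                      dimnames = list(unclass(universe), names(sets)))
  gammas <- vector("list", plan$f)
  for (fi in seq_along(plan$folds)) {
    fold <- plan$folds[[fi]]
    train <- setdiff(unclass(universe), fold)
    gw <- estimate_internal_weights(col, sets, method = method,
                                    params = params, train_genes = train,
                                    internal_f = internal_f,
                                    transform = transform, b = b,
                                    seed = if (is.null(seed)) NULL
                                           else seed + fi)
    gammas[[fi]] <- gw
    if (integration == "wa") {
      net <- integrate_wa(col, gw)
      scorer <- make_scorer(method, net, params)
      for (k in seq_along(sets)) {
        seeds <- setdiff(intersect(sets[[k]], unclass(universe)), fold)
        if (length(seeds) == 0L) {
          warning("fold ", fi, " holds every positive of '", names(sets)[k],
                  "'; its test scores are 0")
          score_mat[fold, k] <- 0
        } else {
          s <- scorer(seeds)
          score_mat[fold, k] <- s[fold]
        }
      }
    } else {
      for (k in seq_along(sets)) {
        net <- integrate_wap(col, gw, names(sets)[k])
        scorer <- make_scorer(method, net, params)
        seeds <- setdiff(intersect(sets[[k]], unclass(universe)), fold)
        if (length(seeds) == 0L) {
          score_mat[fold, k] <- 0
        } else {
          s <- scorer(seeds)
          score_mat[fold, k] <- s[fold]
        }
      }
    }
  }
  rows <- lapply(seq_along(sets), function(k) {
    s <- score_mat[, k]
    c(auc = ranking_auc(s, sets[[k]]),
      precision_at_recall(s, sets[[k]], recall_levels))
  })
  perf <- do.call(rbind, rows)
  report <- data.frame(disease = names(sets), n_pos = lengths(sets),
                       perf, check.names = FALSE, row.names = NULL,
                       stringsAsFactors = FALSE)
  structure(report, scores = score_mat, plan = plan, gamma = gammas,
            class = c("evaluation_report", "data.frame"))
}

#' Label-shuffling permutation test for a ranking
#'
#' Assesses the robustness of a disease's ranking by redrawing the
#' positive label set uniformly at random `n_shuffles` times (same
#' size as the true set, scores held fixed) and counting how many times
#' m the shuffled-label AUC exceeds the true-label AUC. The p-value is
#' the plain ratio m / n_shuffles; an add-one corrected variant
#' (m + 1) / (n_shuffles + 1) is available behind a flag.
#'
#' @param scores Named numeric vector of gene scores (typically the
#'   cross-validated scores of one disease).
#' @param positives Character vector of true positive genes.
#' @param n_shuffles Number of label shuffles (default 1000).
#' @param seed Optional integer seed.
#' @param add_one Use the (m + 1) / (n + 1) estimator?
#' @return List with `auc` (true-label AUC), `m` (exceedance count) and
#'   `p` (p-value).
#' @export
permutation_test <- function(scores, positives, n_shuffles = 1000L,
                             seed = NULL, add_one = FALSE) {
  if (is.null(names(scores))) stop("scores must be named by gene")
  if (!is.null(seed)) set.seed(seed)
  np <- sum(names(scores) %in% positives)
  nn <- length(scores) - np
  if (np == 0L || nn == 0L) stop("both classes must be non-empty")
  r <- rank(scores, ties.method = "average")
  base <- np * (np + 1) / 2
  denom <- np * nn
  auc_true <- (sum(r[names(scores) %in% positives]) - base) / denom
  n <- length(scores)
  m <- 0L
  for (i in seq_len(n_shuffles)) {
    idx <- sample.int(n, np)
    if ((sum(r[idx]) - base) / denom > auc_true) m <- m + 1L
  }
  p <- if (add_one) (m + 1) / (n_shuffles + 1) else m / n_shuffles
  list(auc = auc_true, m = m, p = p)
}

#' Permutation test over every disease of a report
#'
#' Applies [permutation_test()] to each disease's cross-validated score
#' vector and appends `m` and `p_value` columns to the report.
#'
#' @param report An `evaluation_report` (with its `"scores"` attribute).
#' @param sets The [gene_set_collection()] the report was computed on.
#' @param n_shuffles,seed,add_one Passed to [permutation_test()].
#' @return The report with `m` and `p_value` columns added.
#' @export
add_permutation_pvalues <- function(report, sets, n_shuffles = 1000L,
                                    seed = NULL, add_one = FALSE) {
  sm <- attr(report, "scores")
  if (is.null(sm)) stop("report carries no score matrix")
  if (!is.null(seed)) set.seed(seed)
  res <- lapply(report$disease, function(d) {
    permutation_test(sm[, d], sets[[d]], n_shuffles = n_shuffles,
                     add_one = add_one)
  })
  report$m <- vapply(res, `[[`, 0L, "m")
  report$p_value <- vapply(res, `[[`, 0, "p")
  report
}

#' ECDF-percentile analysis of top unannotated candidates
#'
#' For each disease whose ranking is both accurate (AUC >= `auc_min`)
#' and robust (permutation p-value < `p_max`), takes c = the lowest
#' score among annotated genes, forms the empirical cumulative
#' distribution of all scores >= c (annotated and unannotated pooled),
#' and reports the ECDF percentile of each of the `top` highest-scoring
#' unannotated genes: percentile = 100 x (fraction of pooled scores <=
#' the gene's score). A top unannotated gene scoring below c falls
#' outside the support; it is assigned percentile 0 and flagged.
#' Percentiles near 100 mark unannotated genes scoring on par with the
#' best annotated ones - strong disease-gene candidates.
#'
#' @param report An `evaluation_report` with `p_value` column (see
#'   [add_permutation_pvalues()]).
#' @param sets The [gene_set_collection()] of annotated genes.
#' @param auc_min,p_max Selection thresholds.
#' @param top Number of top unannotated genes per disease.
#' @return List with `candidates` (data.frame: disease, rank, gene,
#'   score, percentile, below_support) and `percentile_counts` (counts
#'   of candidates per percentile decile). Empty (with a message) when
#'   no disease passes the thresholds.
#' @export
candidate_analysis <- function(report, sets, auc_min = 0.975, p_max = 0.01,
                               top = 3L) {
  sm <- attr(report, "scores")
  if (is.null(sm)) stop("report carries no score matrix")
  if (is.null(report$p_value)) stop("report lacks p-values; run add_permutation_pvalues()")
  sel <- which(!is.na(report$auc) & report$auc >= auc_min &
                 report$p_value < p_max)
  if (length(sel) == 0L) {
    message("candidate_analysis: no disease passes AUC >= ", auc_min,
            " and p < ", p_max)
    empty <- data.frame(disease = character(), rank = integer(),
                        gene = character(), score = numeric(),
                        percentile = numeric(), below_support = logical())
    return(list(candidates = empty,
                percentile_counts = table(factor(character(),
                                                 levels = decile_levels()))))
  }
  out <- lapply(sel, function(i) {
    d <- report$disease[i]
    s <- sm[, d]
    ann <- names(s) %in% sets[[d]]
    cmin <- min(s[ann])
    support <- s[s >= cmin]
    unann <- s[!ann]
    ord <- order(-unann, names(unann), method = "radix")
    pick <- utils::head(ord, top)
    pct <- vapply(unann[pick], function(v) {
      if (v < cmin) 0 else 100 * mean(support <= v)
    }, 0)
    data.frame(disease = d, rank = seq_along(pick),
               gene = names(unann)[pick], score = unname(unann[pick]),
               percentile = unname(pct),
               below_support = unname(unann[pick] < cmin),
               stringsAsFactors = FALSE)
  })
  cand <- do.call(rbind, out)
  bins <- cut(cand$percentile, breaks = seq(0, 100, by = 10),
              include.lowest = TRUE, labels = decile_levels())
  list(candidates = cand, percentile_counts = table(bins))
}

decile_levels <- function() {
  paste0("(", seq(0, 90, 10), ",", seq(10, 100, 10), "]")
}
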