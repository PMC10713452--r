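#' Classifier configuration
#'
#' Hyperparameters of the gradient-boosted binary classifier of
#' alternative-splicing-event detectability. Defaults are the tuned
#' values used for the detectability analysis: learning rate 0.05, L1
#' weight 1.15, L2 weight 4.0, minimum child weight 2.0, maximum depth 3,
#' minimum loss reduction 2.0, column subsample 0.3, row subsample 0.65,
#' positive-class weight 4.44, sevenfold cross-validation and 100
#' importance shuffles.
#'
#' @param learning_rate,l1,l2,min_child_weight,max_depth,gamma,colsample,subsample,scale_pos_weight
#'   boosting hyperparameters (xgboost naming: eta, alpha, lambda, ...).
#' @param nrounds number of boosting rounds.
#' @param folds cross-validation folds.
#' @param importance_shuffles permutation-importance repetitions.
#' @param seed RNG seed.
#' @return list of class `model_config`.
#' @export
model_config <- function(learning_rate = 0.05, l1 = 1.15, l2 = 4.0,
                         min_child_weight = 2.0, max_depth = 3L,
                         gamma = 2.0, colsample = 0.3, subsample = 0.65,
                         scale_pos_weight = 4.44, nrounds = 150L,
                         folds = 7L, importance_shuffles = 100L, seed = 1L) {
  stopifnot(folds >= 2L, importance_shuffles >= 1L, max_depth >= 1L)
  structure(list(learning_rate = learning_rate, l1 = l1, l2 = l2,
                 min_child_weight = min_child_weight,
                 max_depth = as.integer(max_depth), gamma = gamma,
                 colsample = colsample, subsample = subsample,
                 scale_pos_weight = scale_pos_weight,
                 nrounds = as.integer(nrounds), folds = as.integer(folds),
                 importance_shuffles = as.integer(importance_shuffles),
                 seed = as.integer(seed)),
            class = "model_config")
}

# soft-threshold used by the L1-regularised leaf objective
.thr_l1 <- function(g, alpha) {
  if (g > alpha) g - alpha else if (g < -alpha) g + alpha else 0
}

.leaf_score <- function(G, H, cfg) .thr_l1(G, cfg$l1)^2 / (H + cfg$l2)
.leaf_weight <- function(G, H, cfg) -.thr_l1(G, cfg$l1) / (H + cfg$l2)

.build_tree <- function(X, g, h, rows, cols, depth, cfg) {
  G <- sum(g[rows]); H <- sum(h[rows])
  leaf <- list(leaf = TRUE, weight = .leaf_weight(G, H, cfg))
  if (depth >= cfg$max_depth || length(rows) < 2L) return(leaf)
  best <- list(gain = 0)
  base <- .leaf_score(G, H, cfg)
  for (f in cols) {
    x <- X[rows, f]
    ord <- order(x)
    xo <- x[ord]; go <- g[rows][ord]; ho <- h[rows][ord]
    cg <- cumsum(go); ch <- cumsum(ho)
    cut_ok <- which(diff(xo) > 0)              # split between distinct values
    for (i in cut_ok) {
      HL <- ch[i]; HR <- H - HL
      if (HL < cfg$min_child_weight || HR < cfg$min_child_weight) next
      GL <- cg[i]; GR <- G - GL
      gain <- 0.5 * (.leaf_score(GL, HL, cfg) + .leaf_score(GR, HR, cfg) -
                       base) - cfg$gamma
      if (gain > best$gain)
        best <- list(gain = gain, f = f,
                     split = (xo[i] + xo[i + 1L]) / 2)
    }
  }
  if (best$gain <= 0) return(leaf)
  left <- rows[X[rows, best$f] < best$split]
  right <- rows[X[rows, best$f] >= best$split]
  list(leaf = FALSE, feature = best$f, split = best$split,
       left = .build_tree(X, g, h, left, cols, depth + 1L, cfg),
       right = .build_tree(X, g, h, right, cols, depth + 1L, cfg))
}

.predict_tree <- function(tree, X, rows = seq_len(nrow(X))) {
  out <- numeric(nrow(X))
  rec <- function(node, idx) {
    if (!length(idx)) return()
    if (node$leaf) { out[idx] <<- node$weight; return() }
    go_left <- X[idx, node$feature] < node$split
    rec(node$left, idx[go_left])
    rec(node$right, idx[!go_left])
  }
  rec(tree, rows)
  out
}

#' Train a gradient-boosted tree classifier
#'
#' Self-contained second-order gradient boosting on logistic loss with
#' the standard regularised-tree objective: split gain from
#' gradient/hessian sums with L1 soft-thresholding, L2 shrinkage, minimum
#' loss reduction (gamma) pruning, minimum child hessian weight, per-tree
#' row and column subsampling, and positive-class weighting.
#'
#' @param X numeric feature matrix (rows = events).
#' @param y 0/1 labels.
#' @param cfg a [model_config()].
#' @return object of class `gbt_model` (list of trees + metadata).
#' @export
gbt_train <- function(X, y, cfg = model_config()) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), all(y %in% c(0, 1)))
  if (length(unique(y)) < 2L) stop("training labels contain a single class")
  n <- nrow(X); p <- ncol(X)
  w <- ifelse(y == 1, cfg$scale_pos_weight, 1)
  margin <- numeric(n)
  trees <- vector("list", cfg$nrounds)
  set.seed(cfg$seed)
  n_sub <- max(2L, floor(n * cfg$subsample))
  p_sub <- max(1L, round(p * cfg$colsample))
  for (t in seq_len(cfg$nrounds)) {
    prob <- stats::plogis(margin)
    g <- w * (prob - y)
    h <- pmax(w * prob * (1 - prob), 1e-12)
    rows <- sort(sample.int(n, n_sub))
    cols <- sort(sample.int(p, p_sub))
    tree <- .build_tree(X, g, h, rows, cols, 0L, cfg)
    trees[[t]] <- tree
    margin <- margin + cfg$learning_rate * .predict_tree(tree, X)
  }
  structure(list(trees = trees, cfg = cfg, n_features = p,
                 feature_names = colnames(X)),
            class = "gbt_model")
}

#' Predict detection probabilities
#'
#' @param object a [gbt_train()] model.
#' @param newdata feature matrix.
#' @param ... unused.
#' @return numeric vector of probabilities.
#' @export
predict.gbt_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  stopifnot(ncol(X) == object$n_features)
  margin <- numeric(nrow(X))
  for (tree in object$trees)
    margin <- margin + object$cfg$learning_rate * .predict_tree(tree, X)
  stats::plogis(margin)
}

#' Area under the ROC curve
#'
#' Rank-statistic (Mann-Whitney) AUC; tied scores contribute 1/2.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 labels.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  pos <- labels == 1
  n1 <- sum(pos); n2 <- sum(!pos)
  if (n1 == 0L || n2 == 0L) stop("AUC needs both classes")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

roc_curve <- function(scores, labels) {
  ord <- order(-scores)
  tp <- cumsum(labels[ord] == 1); fp <- cumsum(labels[ord] == 0)
  data.table::data.table(fpr = c(0, fp / max(1, sum(labels == 0))),
                         tpr = c(0, tp / max(1, sum(labels == 1))))
}

stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Cross-validated training and evaluation
#'
#' Stratified k-fold cross-validation (default sevenfold): each fold is
#' held out once, a model is trained on the remainder, and out-of-fold
#' probabilities are evaluated by per-fold ROC/AUC and by the AUC of the
#' pooled out-of-fold predictions.
#'
#' @param X feature matrix; @param y 0/1 labels; @param cfg a
#'   [model_config()].
#' @return list: `auc_per_fold`, `auc_pooled`, `roc_per_fold` (list of
#'   `data.table`s), `oof` (`data.table`: `row`, `fold`, `score`,
#'   `label`), `folds` (fold assignment), `model` (fit on all data).
#' @export
train_eval <- function(X, y, cfg = model_config()) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y))
  if (length(unique(y)) < 2L) stop("labels contain a single class")
  fold <- stratified_folds(y, cfg$folds, cfg$seed)
  if (any(tapply(y, fold, function(v) length(unique(v))) < 2L))
    stop("a fold lost one class; need more data or fewer folds")
  scores <- numeric(length(y))
  auc_fold <- numeric(cfg$folds)
  rocs <- vector("list", cfg$folds)
  for (f in seq_len(cfg$folds)) {
    tr <- fold != f
    cfg_f <- cfg; cfg_f$seed <- cfg$seed + f
    m <- gbt_train(X[tr, , drop = FALSE], y[tr], cfg_f)
    s <- predict(m, X[!tr, , drop = FALSE])
    scores[!tr] <- s
    auc_fold[f] <- auc(s, y[!tr])
    rocs[[f]] <- roc_curve(s, y[!tr])
  }
  list(auc_per_fold = auc_fold,
       auc_pooled = auc(scores, y),
       roc_per_fold = rocs,
       oof = data.table::data.table(row = seq_along(y), fold = fold,
                                    score = scores, label = y),
       folds = fold,
       model = gbt_train(X, y, cfg))
}

#' Permutation feature importance
#'
#' Importance of a feature is the mean drop in AUC when its column is
#' randomly permuted, averaged over `cfg$importance_shuffles` shuffles
#' (default 100), with the standard deviation across shuffles.
#'
#' @param model a [gbt_train()] model.
#' @param X,y evaluation data.
#' @param cfg a [model_config()] (supplies shuffle count and seed).
#' @return `data.table`: `feature`, `importance_mean`, `importance_sd`,
#'   sorted by decreasing mean.
#' @export
permutation_importance <- function(model, X, y, cfg = model$cfg) {
  X <- as.matrix(X)
  base <- auc(predict(model, X), y)
  set.seed(cfg$seed)
  p <- ncol(X)
  nm <- colnames(X) %||% paste0("f", seq_len(p))
  drops <- matrix(NA_real_, cfg$importance_shuffles, p)
  for (s in seq_len(cfg$importance_shuffles)) {
    for (f in seq_len(p)) {
      Xp <- X
      Xp[, f] <- X[sample.int(nrow(X)), f]
      drops[s, f] <- base - auc(predict(model, Xp), y)
    }
  }
  out <- data.table::data.table(feature = nm,
                                importance_mean = colMeans(drops),
                                importance_sd = apply(drops, 2, stats::sd))
  data.table::setorder(out, -importance_mean)
  out[]
}

#' Feature table for the detectability classifier
#'
#' Builds one row per cassette event: transcript abundance (log2
#' RPKM-like), PSI, cassette-exon length, CDS length, frame-preserving
#' flag, and the minimum theoretical junction-region peptide coverage
#' between the two isoforms for each protease. Events on genes without
#' RNA support (zero / missing abundance) are excluded; the exclusion
#' count is in attribute `n_excluded`.
#'
#' @param events `data.frame` with per-event columns `gene_id`, `psi`,
#'   `exon_len`, `cds_len`, `frame_preserving`, `abundance`, and the
#'   isoform/junction descriptors `incl_isoform`, `skip_isoform`,
#'   `incl_junction_aa` (list of residue positions), `skip_junction_aa`.
#' @param proteins named character vector of isoform protein sequences.
#' @param rules protease rules ([protease_rules()]).
#' @param params digestion window ([digest_params()]).
#' @param window residues on each side of a junction that define the
#'   junction region for the coverage feature (default 35, the maximum
#'   detectable peptide length).
#' @return numeric feature matrix with rownames = event ids.
#' @export
featurize <- function(events, proteins, rules = protease_rules(),
                      params = digest_params(), window = 35L) {
  ev <- data.table::as.data.table(events)
  keep <- !is.na(ev$abundance) & ev$abundance > 0
  n_excluded <- sum(!keep)
  ev <- ev[keep]
  base <- cbind(abundance_log2 = log2(ev$abundance),
                psi = ev$psi,
                exon_len = ev$exon_len,
                cds_len = ev$cds_len,
                frame_preserving = as.numeric(ev$frame_preserving))
  covf <- matrix(NA_real_, nrow(ev), length(rules),
                 dimnames = list(NULL, paste0("jcov_", names(rules))))
  for (r in seq_len(nrow(ev))) {
    for (pn in names(rules)) {
      c_in <- junction_coverable_fraction(proteins[[ev$incl_isoform[r]]],
                                          ev$incl_junction_aa[[r]],
                                          rules[[pn]], params, window)
      c_sk <- junction_coverable_fraction(proteins[[ev$skip_isoform[r]]],
                                          ev$skip_junction_aa[[r]],
                                          rules[[pn]], params, window)
      covf[r, paste0("jcov_", pn)] <- min(c_in, c_sk)
    }
  }
  X <- cbind(base, covf)
  rownames(X) <- if ("event_id" %in% names(ev)) ev$event_id else NULL
  stopifnot(!anyNA(X))
  data.table::setattr(X, "n_excluded", n_excluded)
  X
}

#' Coverable fraction of the junction region of a protein
#'
#' Fraction of the residues within `window` amino acids of the given
#' junction position(s) that lie inside at least one fully specific
#' digestion product retained by the length window.
#'
#' @param protein amino-acid string.
#' @param junction_aa residue positions immediately 5' of each junction.
#' @param rule a [protease_rule()]; @param params a [digest_params()].
#' @param window region half-width in residues.
#' @return fraction in `[0, 1]` (0 when the region is empty).
#' @export
junction_coverable_fraction <- function(protein, junction_aa, rule,
                                        params = digest_params(),
                                        window = 35L) {
  n <- nchar(protein)
  if (n == 0L || !length(junction_aa)) return(0)
  region <- logical(n)
  for (j in junction_aa) {
    lo <- max(1L, j - window + 1L); hi <- min(n, j + window)
    region[lo:hi] <- TRUE
  }
  if (!any(region)) return(0)
  dt <- digest(protein, rule, params)
  covered <- logical(n)
  if (nrow(dt)) for (r in seq_len(nrow(dt)))
    covered[dt$start[r]:dt$end[r]] <- TRUE
  sum(covered & region) / sum(region)
}
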