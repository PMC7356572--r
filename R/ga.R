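# Real-coded genetic algorithm for classifier hyperparameter tuning:
# tournament selection (size 3), blend (BLX-alpha) crossover, Gaussian
# mutation clipped to the search bounds, elitism, and injection of the
# default hyperparameter set into the initial population so the optimized
# result can never score below the default on the validation set. Fitness
# is the validation AUC of a model trained on the training set.

#' Genetic-algorithm configuration
#'
#' @param population Population size.
#' @param generations Number of generations.
#' @param crossover_rate,mutation_rate Per-pair crossover and per-gene
#'   mutation probabilities, in [0, 1].
#' @param elitism Number of top individuals copied unchanged into the next
#'   generation.
#' @param seed Integer seed for the whole GA run (and model training).
#' @param bounds Optional named list of `c(lo, hi)` per gene, overriding
#'   the classifier's default search box.
#' @return A list of class `ga_config`.
#' @export
ga_config <- function(population = 50L, generations = 30L,
                      crossover_rate = 0.9, mutation_rate = 0.1,
                      elitism = 2L, seed = 1L, bounds = NULL) {
  if (crossover_rate < 0 || crossover_rate > 1 ||
      mutation_rate < 0 || mutation_rate > 1)
    stop_contract("rates must lie in [0, 1]")
  structure(list(population = as.integer(population),
                 generations = as.integer(generations),
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 elitism = as.integer(elitism), seed = as.integer(seed),
                 bounds = bounds), class = "ga_config")
}

# Default search boxes. C and gamma move on a log2 scale; tree counts and
# layer widths are integers. Boxes cover the hyperparameter magnitudes
# typically reported for this problem (e.g. C near 100, gamma near 10,
# slopes/intercepts around +/-15, hundreds of trees or neurons).
ga_genes <- function(classifier, n_features) {
  switch(classifier,
    svm_linear = list(
      log2_C = list(bounds = c(-5, 7), integer = FALSE)),
    svm_rbf = list(
      log2_C = list(bounds = c(-5, 7), integer = FALSE),
      log2_gamma = list(bounds = c(-10, 4), integer = FALSE)),
    svm_sigmoid = list(
      log2_C = list(bounds = c(-5, 7), integer = FALSE),
      slope = list(bounds = c(-15, 15), integer = FALSE),
      intercept = list(bounds = c(-15, 15), integer = FALSE)),
    rf = list(
      n_trees = list(bounds = c(1, 500), integer = TRUE)),
    ann = list(
      neurons1 = list(bounds = c(1, 500), integer = TRUE),
      neurons2 = list(bounds = c(1, 500), integer = TRUE),
      neurons3 = list(bounds = c(1, 500), integer = TRUE),
      neurons4 = list(bounds = c(1, 500), integer = TRUE))
  )
}

ga_decode <- function(classifier, genome, genes) {
  g <- as.list(genome)
  names(g) <- names(genes)
  for (nm in names(genes))
    if (genes[[nm]]$integer) g[[nm]] <- as.integer(round(g[[nm]]))
  switch(classifier,
    svm_linear = hyperparameter_set("svm_linear", C = 2^g$log2_C),
    svm_rbf = hyperparameter_set("svm_rbf", C = 2^g$log2_C,
                                 gamma = 2^g$log2_gamma),
    svm_sigmoid = hyperparameter_set("svm_sigmoid", C = 2^g$log2_C,
                                     slope = g$slope,
                                     intercept = g$intercept),
    rf = hyperparameter_set("rf", n_trees = g$n_trees),
    ann = hyperparameter_set("ann",
                             neurons = c(g$neurons1, g$neurons2,
                                         g$neurons3, g$neurons4))
  )
}

# genome of the default hyperparameter set, for injection
ga_default_genome <- function(classifier, n_features, genes) {
  clip <- function(v, nm) min(max(v, genes[[nm]]$bounds[1]),
                              genes[[nm]]$bounds[2])
  g <- switch(classifier,
    svm_linear = c(log2_C = 0),
    svm_rbf = c(log2_C = 0, log2_gamma = log2(1 / n_features)),
    svm_sigmoid = c(log2_C = 0, slope = 1 / n_features, intercept = 0),
    rf = c(n_trees = 500),
    ann = c(neurons1 = 1, neurons2 = 1, neurons3 = 1, neurons4 = 1))
  vapply(names(g), function(nm) clip(g[[nm]], nm), numeric(1))
}

#' Optimize classifier hyperparameters with a genetic algorithm
#'
#' Maximizes the validation AUC of a model trained on `train` and scored on
#' `val` (which must be patient-disjoint). The default hyperparameter set
#' is injected into the initial population and elitism preserves the best
#' individual, so the returned AUC is never below the default
#' configuration's. Returns the best individual ever evaluated.
#'
#' @param classifier One of the supported classifier kinds.
#' @param train,val Patient-disjoint [labeled_spectra()] sets, each with
#'   both lesion classes.
#' @param cfg A [ga_config()].
#' @return A list of class `ga_result`: `best_hp` (a
#'   [hyperparameter_set()]), `best_auc`, `default_auc`, and `history`
#'   (best-so-far AUC per generation).
#' @export
ga_optimize <- function(classifier, train, val, cfg = ga_config()) {
  classifier <- match.arg(classifier, .classifiers)
  stopifnot(inherits(train, "labeled_spectra"),
            inherits(val, "labeled_spectra"))
  shared <- intersect(unique(train$patient_id), unique(val$patient_id))
  if (length(shared))
    stop_contract("train and validation share patients: ",
                  paste(shared, collapse = ", "))
  vd <- lesion_xy(val)
  if (length(unique(vd$y)) < 2L)
    stop_contract("validation set must contain both lesion classes")
  nf <- ncol(train$spectra)
  genes <- ga_genes(classifier, nf)
  if (!is.null(cfg$bounds))
    for (nm in names(cfg$bounds)) {
      if (!nm %in% names(genes)) stop_contract("unknown gene: ", nm)
      genes[[nm]]$bounds <- as.numeric(cfg$bounds[[nm]])
    }
  lo <- vapply(genes, function(g) g$bounds[1], numeric(1))
  hi <- vapply(genes, function(g) g$bounds[2], numeric(1))
  ng <- length(genes)

  cache <- new.env(parent = emptyenv())
  fitness <- function(genome) {
    key <- paste(signif(genome, 12), collapse = "|")
    if (!is.null(cache[[key]])) return(cache[[key]])
    hp <- ga_decode(classifier, genome, genes)
    auc <- tryCatch({
      model <- train_classifier(train, hp, seed = cfg$seed)
      pr <- predict(model, vd$x)
      roc_auc(pr$score, vd$y == "malignant")
    }, error = function(e) 0)
    cache[[key]] <- auc
    auc
  }

  with_seed(cfg$seed, {
    pop <- matrix(stats::runif(cfg$population * ng), cfg$population, ng)
    pop <- sweep(sweep(pop, 2L, hi - lo, "*"), 2L, lo, "+")
    pop[1L, ] <- ga_default_genome(classifier, nf, genes)
    fit <- apply(pop, 1L, fitness)
    default_auc <- fit[1L]
    best_genome <- pop[which.max(fit), ]
    best_auc <- max(fit)
    history <- numeric(cfg$generations)
    tournament <- function() {
      cand <- sample.int(cfg$population, 3L)
      cand[which.max(fit[cand])]
    }
    for (gen in seq_len(cfg$generations)) {
      ord <- order(fit, decreasing = TRUE)
      new_pop <- pop[ord[seq_len(min(cfg$elitism, cfg$population))], ,
                     drop = FALSE]
      while (nrow(new_pop) < cfg$population) {
        p1 <- pop[tournament(), ]; p2 <- pop[tournament(), ]
        if (stats::runif(1) < cfg$crossover_rate) {
          # BLX-0.5 blend crossover
          lo_c <- pmin(p1, p2); hi_c <- pmax(p1, p2)
          span <- hi_c - lo_c
          c1 <- stats::runif(ng, lo_c - 0.5 * span, hi_c + 0.5 * span)
          c2 <- stats::runif(ng, lo_c - 0.5 * span, hi_c + 0.5 * span)
        } else {
          c1 <- p1; c2 <- p2
        }
        for (child in list(c1, c2)) {
          mut <- stats::runif(ng) < cfg$mutation_rate
          child[mut] <- child[mut] +
            stats::rnorm(sum(mut), sd = 0.1 * (hi[mut] - lo[mut]))
          child <- pmin(pmax(child, lo), hi)
          if (nrow(new_pop) < cfg$population)
            new_pop <- rbind(new_pop, child)
        }
      }
      pop <- new_pop
      fit <- apply(pop, 1L, fitness)
      if (max(fit) > best_auc) {
        best_auc <- max(fit)
        best_genome <- pop[which.max(fit), ]
      }
      history[gen] <- best_auc
    }
  })
  structure(list(best_hp = ga_decode(classifier, best_genome, genes),
                 best_auc = best_auc, default_auc = default_auc,
                 history = history), class = "ga_result")
}

#' @export
print.ga_result <- function(x, ...) {
  cat(sprintf("<ga_result> %s: best AUC %.4f (default %.4f)\n",
              x$best_hp$classifier, x$best_auc, x$default_auc))
  invisible(x)
}
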