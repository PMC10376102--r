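#' Genetic-algorithm configuration for wrapper feature selection
#'
#' One gene per feature column; fitness of a chromosome is the [objfit()]
#' of pooled out-of-fold predictions from a gradient-boosted regressor
#' trained on the masked columns under chain-level cross-validation. The
#' fitness regressor follows the selection-stage settings (depth 6,
#' learning rate 0.1, 100 rounds, min child weight 5, row subsample 0.9,
#' histogram trees with 500 bins).
#'
#' @param population_size Chromosomes per generation.
#' @param generations Number of generations to evolve.
#' @param elite_count Top chromosomes copied unchanged each generation.
#' @param crossover_rate Probability of single-point crossover per pair.
#' @param mutation_rate Per-gene bit-flip probability; `NULL` (default)
#'   means 1/D for a D-gene chromosome.
#' @param seed Integer seed governing all GA and fitness randomness.
#' @param fitness_cv_folds Chain-level folds inside the fitness evaluation.
#' @param fitness_config [regressor_config()] used by the fitness
#'   regressor.
#' @return Object of class `taf_ga_config`.
#' @export
ga_config <- function(population_size = 50, generations = 30, elite_count = 2,
                      crossover_rate = 0.9, mutation_rate = NULL, seed = 1,
                      fitness_cv_folds = 3,
                      fitness_config = regressor_config(
                        learning_rate = 0.1, n_estimators = 100, max_depth = 6,
                        num_leaves = 64, max_bin = 500, feature_fraction = 1,
                        min_child_weight = 5, subsample = 0.9, seed = seed)) {
  stopifnot(population_size >= 2, generations >= 1,
            elite_count >= 0, elite_count < population_size,
            crossover_rate >= 0, crossover_rate <= 1,
            is.null(mutation_rate) || (mutation_rate >= 0 && mutation_rate <= 1),
            fitness_cv_folds >= 2)
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 elite_count = as.integer(elite_count),
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 seed = as.integer(seed),
                 fitness_cv_folds = as.integer(fitness_cv_folds),
                 fitness_config = fitness_config),
            class = "taf_ga_config")
}

#' Fitness of a feature mask
#'
#' Trains the fitness regressor on the masked columns under chain-level
#' k-fold cross-validation and scores the pooled out-of-fold predictions
#' with [objfit()]. Deterministic for a fixed configuration seed. An empty
#' mask scores `-Inf` so it can never be selected.
#'
#' @param mask Logical (or 0/1) vector over feature columns.
#' @param x Feature tibble or matrix (typically windowed, rows pooled over
#'   chains).
#' @param y Labels row-aligned with `x`.
#' @param chain_ids Chain id per row.
#' @param cfg A [ga_config()].
#' @return Scalar fitness (objfit scale).
#' @export
evaluate_fitness <- function(mask, x, y, chain_ids, cfg = ga_config()) {
  mask <- as.logical(mask)
  if (!any(mask)) return(-Inf)
  X <- if (is.matrix(x)) x else feature_matrix(x)
  Xm <- X[, mask, drop = FALSE]
  folds <- chain_level_folds(chain_ids, k = cfg$fitness_cv_folds, seed = cfg$seed)
  fold_of <- folds$fold[match(chain_ids, folds$chain_id)]
  pred <- rep(NA_real_, length(y))
  for (f in seq_len(cfg$fitness_cv_folds)) {
    test <- fold_of == f
    booster <- fit_gbt(Xm[!test, , drop = FALSE], y[!test], cfg$fitness_config)
    pred[test] <- predict_gbt(booster, Xm[test, , drop = FALSE])
  }
  objfit(mae(pred, y), pcc(pred, y))
}

# fitness-proportional (roulette) parent sampling; fitnesses are windowed
# by the generation minimum so that selection pressure survives a narrow
# fitness range
roulette_pick <- function(fitness, n) {
  w <- fitness - min(fitness)
  rng <- max(fitness) - min(fitness)
  w <- w + if (rng > 0) 0.1 * rng else 1
  sample.int(length(fitness), n, replace = TRUE, prob = w)
}

#' One generation of the genetic algorithm
#'
#' The top `elite_count` chromosomes are copied unchanged; the remainder
#' are produced by roulette parent selection, single-point crossover with
#' probability `crossover_rate`, and per-gene bit-flip mutation. Population
#' size is preserved. Uses the current RNG state; seed management belongs
#' to [select_features()].
#'
#' @param pop Logical matrix, one chromosome per row.
#' @param fitness Numeric vector of chromosome fitnesses.
#' @param cfg A [ga_config()].
#' @return Logical matrix of the next generation.
#' @export
evolve <- function(pop, fitness, cfg = ga_config()) {
  n <- nrow(pop)
  D <- ncol(pop)
  if (length(fitness) != n) abort("`fitness` must have one entry per chromosome")
  if (all(!is.finite(fitness))) abort("all chromosomes have sentinel fitness")
  mut <- cfg$mutation_rate %||% (1 / D)
  elite_idx <- head(order(fitness, decreasing = TRUE), cfg$elite_count)
  children <- matrix(FALSE, nrow = n - cfg$elite_count, ncol = D)
  i <- 1L
  while (i <= nrow(children)) {
    parents <- roulette_pick(fitness, 2L)
    c1 <- pop[parents[1], ]
    c2 <- pop[parents[2], ]
    if (D > 1L && runif(1) < cfg$crossover_rate) {
      cut <- sample.int(D - 1L, 1L)
      tmp <- c1
      c1 <- c(c1[seq_len(cut)], c2[(cut + 1L):D])
      c2 <- c(c2[seq_len(cut)], tmp[(cut + 1L):D])
    }
    for (child in list(c1, c2)) {
      if (i > nrow(children)) break
      flip <- runif(D) < mut
      children[i, ] <- xor(child, flip)
      i <- i + 1L
    }
  }
  rbind(pop[elite_idx, , drop = FALSE], children)
}

#' Wrapper feature selection with a genetic algorithm
#'
#' Evolves a population of binary feature masks from a uniform-random
#' start, scoring each mask with [evaluate_fitness()] (results are cached,
#' so elites are never re-evaluated). Fully reproducible from the
#' configuration seed.
#'
#' @param x Feature tibble or matrix (rows pooled over chains).
#' @param y Labels row-aligned with `x`.
#' @param chain_ids Chain id per row (taken from `x` when omitted).
#' @param cfg A [ga_config()].
#' @return Object of class `taf_ga`: `best_mask` (named logical vector),
#'   `best_fitness`, a per-generation `history` tibble, and the config.
#' @export
select_features <- function(x, y, chain_ids = NULL, cfg = ga_config()) {
  X <- if (is.matrix(x)) x else feature_matrix(x)
  if (is.null(chain_ids) && !is.matrix(x) && "chain_id" %in% names(x)) {
    chain_ids <- x$chain_id
  }
  if (is.null(chain_ids)) abort("`chain_ids` is required")
  D <- ncol(X)
  if (all(apply(X, 2, sd) == 0)) {
    warn("all feature columns are constant; selection is uninformative")
  }
  cache <- new.env(parent = emptyenv())
  fit1 <- function(mask) {
    key <- paste(as.integer(mask), collapse = "")
    if (!is.null(cache[[key]])) return(cache[[key]])
    f <- evaluate_fitness(mask, X, y, chain_ids, cfg)
    cache[[key]] <- f
    f
  }
  withr::with_seed(cfg$seed, {
    pop <- matrix(runif(cfg$population_size * D) < 0.5,
                  nrow = cfg$population_size)
    for (i in seq_len(cfg$population_size)) {
      if (!any(pop[i, ])) pop[i, sample.int(D, 1L)] <- TRUE
    }
    best_mask <- NULL
    best_fit <- -Inf
    history <- vector("list", cfg$generations)
    for (g in seq_len(cfg$generations)) {
      fitness <- vapply(seq_len(nrow(pop)), function(i) fit1(pop[i, ]), 0)
      top <- which.max(fitness)
      if (fitness[top] > best_fit) {
        best_fit <- fitness[top]
        best_mask <- pop[top, ]
      }
      history[[g]] <- tibble(generation = g,
                             best_fitness = best_fit,
                             generation_best = max(fitness),
                             mean_fitness = mean(fitness[is.finite(fitness)]),
                             mean_active = mean(rowSums(pop)))
      if (g < cfg$generations) pop <- evolve(pop, fitness, cfg)
    }
  })
  names(best_mask) <- colnames(X) %||% paste0("f", seq_len(D))
  structure(list(best_mask = best_mask, best_fitness = best_fit,
                 history = bind_rows(history), config = cfg),
            class = "taf_ga")
}

#' @export
print.taf_ga <- function(x, ...) {
  cat(sprintf("<taf_ga> %d/%d features selected, best fitness %.4f after %d generations\n",
              sum(x$best_mask), length(x$best_mask), x$best_fitness,
              x$config$generations))
  invisible(x)
}

#' @rdname select_features
#' @param x A `taf_ga` object.
#' @param ... Unused.
#' @method tidy taf_ga
#' @export
tidy.taf_ga <- function(x, ...) {
  x$history
}

#' @rdname select_features
#' @method glance taf_ga
#' @export
glance.taf_ga <- function(x, ...) {
  tibble(n_selected = sum(x$best_mask), n_features = length(x$best_mask),
         best_fitness = x$best_fitness, generations = x$config$generations)
}

#' @rdname select_features
#' @param object A `taf_ga` object.
#' @method autoplot taf_ga
#' @export
autoplot.taf_ga <- function(object, ...) {
  long <- tidyr::pivot_longer(object$history,
                              c("best_fitness", "generation_best", "mean_fitness"),
                              names_to = "series", values_to = "fitness")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$generation, y = .data$fitness,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "generation", y = "objfit = 1 - MAE + PCC",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Serialise / load a GA result as JSON
#'
#' @param ga A `taf_ga` object.
#' @param path Output path.
#' @return `path` invisibly for the writer; a list with `best_mask`,
#'   `best_fitness` and `history` for the reader.
#' @export
write_ga_json <- function(ga, path) {
  jsonlite::write_json(
    list(best_mask = as.integer(ga$best_mask),
         feature_names = names(ga$best_mask),
         best_fitness = ga$best_fitness,
         history = ga$history),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ga_json
#' @export
read_ga_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$best_mask <- setNames(as.logical(raw$best_mask), raw$feature_names)
  raw$history <- as_tibble(raw$history)
  raw
}
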