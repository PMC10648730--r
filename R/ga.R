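# Genetic-algorithm search over the four training hyperparameters: population
# of 10, rank selection keeping the fittest half, single-point crossover,
# per-gene Gaussian mutation with probability 0.2 (the single fittest
# individual is copied unchanged), for a default budget of 25 generations.

GENE_ORDER <- c("learning_rate", "dropout_rate", "start_feature_maps",
                "batch_size")

#' Default gene bounds for the hyperparameter search
#'
#' Learning rate is searched log-uniformly on `[1e-4, 0.3]`; dropout rate
#' uniformly on `[0, 0.5]`; the integer genes over small candidate sets. The
#' ranges bracket the full-scale search optimum (learning rate 0.15, batch
#' size 12, 32 feature maps, dropout 0.1).
#'
#' @return A named list of gene descriptors (`lo`/`hi`/`scale` or
#'   `values`/`scale`).
#' @export
default_gene_bounds <- function() {
  list(
    learning_rate = list(lo = 1e-4, hi = 0.3, scale = "log"),
    dropout_rate = list(lo = 0, hi = 0.5, scale = "linear"),
    start_feature_maps = list(values = c(8, 16, 32, 64), scale = "integer"),
    batch_size = list(values = c(4, 8, 12, 16, 24), scale = "integer")
  )
}

check_bounds <- function(bounds) {
  for (nm in GENE_ORDER) {
    g <- bounds[[nm]]
    if (is.null(g)) stop("missing gene bounds for ", nm)
    if (g$scale == "integer") {
      if (length(g$values) < 1) stop("no candidate values for ", nm)
    } else if (g$lo > g$hi) {
      stop("inverted bounds for ", nm, ": [", g$lo, ", ", g$hi, "]")
    }
  }
  bounds
}

sample_gene <- function(g) {
  switch(g$scale,
         log = 10^runif(1, log10(g$lo), log10(g$hi)),
         linear = runif(1, g$lo, g$hi),
         integer = if (length(g$values) == 1) g$values
                   else sample(g$values, 1))
}

clip_gene <- function(value, g) {
  switch(g$scale,
         log = min(max(value, g$lo), g$hi),
         linear = min(max(value, g$lo), g$hi),
         integer = g$values[which.min(abs(g$values - value))])
}

mutate_gene <- function(value, g, sd_fraction = 0.2) {
  newv <- switch(g$scale,
    log = {
      l <- log10(value)
      10^(l + rnorm(1, 0, sd_fraction * max(abs(l), 0.1)))
    },
    linear = value + rnorm(1, 0, sd_fraction * max(abs(value), 0.01)),
    integer = value + rnorm(1, 0, sd_fraction * max(abs(value), 1)))
  clip_gene(newv, g)
}

#' Initialise a GA population
#'
#' Draws `size` individuals (default 10), each a set of the four training
#' hyperparameters, independently within the gene bounds; the learning rate
#' is drawn log-uniformly. Deterministic for a fixed seed.
#'
#' @param bounds Gene bounds as from [default_gene_bounds()].
#' @param seed Integer seed.
#' @param size Population size (default 10).
#' @return An object of class `ga_state`.
#' @export
init_population <- function(bounds = default_gene_bounds(), seed = 1L,
                            size = 10L) {
  bounds <- check_bounds(bounds)
  set.seed(seed)
  population <- lapply(seq_len(size), function(i) {
    ind <- lapply(bounds[GENE_ORDER], sample_gene)
    names(ind) <- GENE_ORDER
    ind
  })
  structure(list(population = population, bounds = bounds,
                 fitness = rep(NA_real_, size), generation = 0L,
                 best = NULL, best_fitness = -Inf, size = size,
                 log = NULL, seed = seed),
            class = "ga_state")
}

#' @export
print.ga_state <- function(x, ...) {
  cat(sprintf("GA state: population %d, generation %d, best fitness %s\n",
              x$size, x$generation,
              if (is.finite(x$best_fitness))
                sprintf("%.4g", x$best_fitness) else "unevaluated"))
  if (!is.null(x$best)) {
    cat(sprintf("  best: lr=%.4g dropout=%.3f maps=%d batch=%d\n",
                x$best$learning_rate, x$best$dropout_rate,
                as.integer(x$best$start_feature_maps),
                as.integer(x$best$batch_size)))
  }
  invisible(x)
}

eval_fitness <- function(fitness_fn, ind) {
  tryCatch(fitness_fn(ind), error = function(e) {
    message("fitness evaluation failed (", conditionMessage(e),
            "); assigning worst fitness")
    -Inf
  })
}

single_point_crossover <- function(p1, p2, point) {
  child <- p1
  child[GENE_ORDER[(point + 1):4]] <- p2[GENE_ORDER[(point + 1):4]]
  child
}

#' Evolve a GA population
#'
#' Runs the generational loop: rank by fitness, keep the fittest half,
#' refill the population by single-point crossover of parent pairs drawn
#' uniformly with replacement from the survivors (crossover point uniform
#' over the three cut positions of the 4-gene vector), then subject every
#' gene of every individual except the single fittest to Gaussian mutation
#' with probability `mutation_prob`, clipping to the gene bounds. Elitism
#' guarantees the best-ever fitness is non-decreasing.
#'
#' @param state A `ga_state` from [init_population()].
#' @param fitness_fn Function taking a named hyperparameter list and
#'   returning a scalar fitness (higher is fitter). Errors are caught and
#'   scored as worst fitness.
#' @param generations Number of generations (default 25).
#' @param mutation_prob Per-gene mutation probability (default 0.2).
#' @param mutation_sd Mutation standard deviation as a fraction of the gene
#'   value on its native scale (default 0.2).
#' @return The updated `ga_state`; `$best` holds the best-ever individual,
#'   `$log` a per-generation data frame of all genes and fitnesses.
#' @export
evolve <- function(state, fitness_fn, generations = 25,
                   mutation_prob = 0.2, mutation_sd = 0.2) {
  stopifnot(inherits(state, "ga_state"))
  bounds <- state$bounds
  size <- state$size
  n_keep <- ceiling(size / 2)
  logs <- if (is.null(state$log)) list() else list(state$log)
  for (gen in seq_len(generations)) {
    state$generation <- state$generation + 1L
    for (i in seq_len(size)) {
      if (is.na(state$fitness[i])) {
        state$fitness[i] <- eval_fitness(fitness_fn, state$population[[i]])
      }
    }
    ord <- order(state$fitness, decreasing = TRUE)
    if (state$fitness[ord[1]] > state$best_fitness) {
      state$best_fitness <- state$fitness[ord[1]]
      state$best <- state$population[[ord[1]]]
    }
    logs[[length(logs) + 1L]] <- data.frame(
      generation = state$generation,
      individual = seq_len(size),
      do.call(rbind, lapply(state$population, function(p)
        as.data.frame(p[GENE_ORDER]))),
      fitness = state$fitness,
      best_ever = state$best_fitness)
    # selection: fittest half survives
    survivors <- state$population[ord[seq_len(n_keep)]]
    surv_fit <- state$fitness[ord[seq_len(n_keep)]]
    children <- vector("list", size - n_keep)
    for (j in seq_along(children)) {
      pair <- sample(n_keep, 2, replace = TRUE)
      point <- sample(3, 1)
      children[[j]] <- single_point_crossover(survivors[[pair[1]]],
                                              survivors[[pair[2]]], point)
    }
    population <- c(survivors, children)
    fitness <- c(surv_fit, rep(NA_real_, length(children)))
    # mutation: every gene of every individual except the single fittest
    for (i in seq_along(population)) {
      if (i == 1L) next  # elite, copied unchanged
      mutated <- FALSE
      for (nm in GENE_ORDER) {
        if (runif(1) < mutation_prob) {
          population[[i]][[nm]] <- mutate_gene(population[[i]][[nm]],
                                               bounds[[nm]], mutation_sd)
          mutated <- TRUE
        }
      }
      if (mutated) fitness[i] <- NA_real_
    }
    state$population <- population
    state$fitness <- fitness
  }
  state$log <- do.call(rbind, logs)
  state
}

#' Hyperparameters of the best individual
#'
#' @param state An evolved `ga_state`.
#' @return A [hyperparameters()] object.
#' @export
best_hyperparameters <- function(state) {
  stopifnot(inherits(state, "ga_state"), !is.null(state$best))
  hyperparameters(learning_rate = state$best$learning_rate,
                  dropout_rate = state$best$dropout_rate,
                  start_feature_maps = state$best$start_feature_maps,
                  batch_size = state$best$batch_size)
}

#' CNN-training fitness function
#'
#' Builds the fitness used by the hyperparameter search: the negative best
#' validation loss of a short training run on a fixed random subset
#' (25\% by default) of the side dataset. The subset is drawn once, so all
#' individuals are scored on identical data; identical hyperparameters with
#' an identical seed receive identical fitness. Training divergence scores
#' as worst fitness.
#'
#' @param dataset A `side_dataset`.
#' @param input_shape Model input shape used for the evaluation runs.
#' @param dataset_fraction Fraction of the dataset used (default 0.25).
#' @param epoch_budget Training epochs per evaluation.
#' @param seed Integer seed fixing the subset and the evaluation training
#'   runs.
#' @return A function `f(hp_list) -> fitness`.
#' @export
cnn_fitness <- function(dataset, input_shape = dim(dataset$slices[[1]]$image),
                        dataset_fraction = 0.25, epoch_budget = 3,
                        seed = 1L) {
  stopifnot(inherits(dataset, "side_dataset"), length(dataset$slices) >= 8)
  set.seed(seed)
  n <- length(dataset$slices)
  keep <- sort(sample(n, max(5L, round(dataset_fraction * n))))
  sub <- dataset
  sub$slices <- dataset$slices[keep]
  function(ind) {
    hp <- hyperparameters(learning_rate = ind$learning_rate,
                          dropout_rate = ind$dropout_rate,
                          start_feature_maps = ind$start_feature_maps,
                          batch_size = ind$batch_size)
    res <- tryCatch({
      net <- build_unet(hp, input_shape, seed = seed)
      train_unet(net, sub, patience = epoch_budget + 1L,
                 max_epochs = epoch_budget, augment_prob = 0,
                 seed = seed, verbose = FALSE)
    }, error = function(e) NULL)
    if (is.null(res)) return(-Inf)
    -res$best_val_loss
  }
}
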