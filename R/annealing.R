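#' Simulated-annealing configuration
#'
#' Defaults follow the two-stage calibration protocol: 25 independent
#' runs of 5000 steps seeded from the initial matrix with initial
#' deleterious-acceptance probability 0.80, then 25 runs of 25000 steps
#' seeded from the stage-1 best with initial acceptance 0.10. The
#' acceptance probability cools geometrically by a factor 0.002 per step,
#' perturbations rescale an entry by `1 + f` with `f ~ U(-0.6, 0.6)`, and
#' per step an influence is added to an empty off-diagonal cell with
#' probability 0.001 or an existing off-diagonal influence removed with
#' probability 0.01.
#'
#' @param n_runs runs per stage.
#' @param steps_stage1,steps_stage2 steps per run in each stage.
#' @param p_accept0_stage1,p_accept0_stage2 initial probability of
#'   accepting a deleterious perturbation in each stage.
#' @param cooling per-step geometric cooling factor.
#' @param perturb_range bound of the uniform relative perturbation `f`.
#' @param p_add probability per step of adding a new influence.
#' @param p_remove probability per step of removing an influence.
#' @param seed integer seed from which all run seeds are derived.
#' @return An object of class `sa_config`.
#' @export
sa_config <- function(n_runs = 25, steps_stage1 = 5000, steps_stage2 = 25000,
                      p_accept0_stage1 = 0.80, p_accept0_stage2 = 0.10,
                      cooling = 0.002, perturb_range = 0.6,
                      p_add = 0.001, p_remove = 0.01, seed = 1L) {
  probs <- c(p_accept0_stage1, p_accept0_stage2, p_add, p_remove)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0,1]", call. = FALSE)
  if (p_add + p_remove > 1) stop("p_add + p_remove must not exceed 1", call. = FALSE)
  if (steps_stage1 < 0 || steps_stage2 < 0) stop("steps must be >= 0", call. = FALSE)
  if (n_runs < 1) stop("n_runs must be >= 1", call. = FALSE)
  if (perturb_range <= 0) stop("perturb_range must be positive", call. = FALSE)
  structure(list(n_runs = as.integer(n_runs),
                 steps_stage1 = as.integer(steps_stage1),
                 steps_stage2 = as.integer(steps_stage2),
                 p_accept0_stage1 = p_accept0_stage1,
                 p_accept0_stage2 = p_accept0_stage2,
                 cooling = cooling, perturb_range = perturb_range,
                 p_add = p_add, p_remove = p_remove,
                 seed = as.integer(seed)),
            class = "sa_config")
}

#' Propose one perturbation of an influence matrix
#'
#' Exactly one move per call, chosen by a single uniform draw `u`:
#' `u < p_add` adds an influence (a uniformly chosen zero off-diagonal
#' cell is set to a draw from `U(-f, f)`); otherwise `u < p_add +
#' p_remove` removes one (a uniformly chosen nonzero off-diagonal cell is
#' set to 0); otherwise a uniformly chosen nonzero cell — diagonal
#' included — is rescaled to `y * (1 + f)` with `f ~ U(-f_max, f_max)`.
#' If the required cell class is empty the move degrades to a rescale.
#' Diagonal (decay) entries can be rescaled but never removed, so the
#' per-cluster decay stays defined.
#'
#' @param model an [influence_model()].
#' @param config an [sa_config()].
#' @return List with `model` (perturbed copy) and `move`
#'   ("add" / "remove" / "tweak"). Consumes the R random-number stream.
#' @export
perturb_matrix <- function(model, config) {
  A <- model$A
  K <- nrow(A)
  off <- !diag(TRUE, K)
  nonzero <- which(A != 0)
  if (length(nonzero) == 0) stop("model has no nonzero entries", call. = FALSE)
  zeros_off <- which(off & A == 0)
  nonzero_off <- which(off & A != 0)
  u <- runif(1)
  move <- if (u < config$p_add) "add"
          else if (u < config$p_add + config$p_remove) "remove"
          else "tweak"
  if (move == "add" && length(zeros_off) == 0) move <- "tweak"
  if (move == "remove" && length(nonzero_off) == 0) move <- "tweak"
  f <- config$perturb_range
  if (move == "add") {
    cell <- zeros_off[sample.int(length(zeros_off), 1)]
    A[cell] <- runif(1, -f, f)
  } else if (move == "remove") {
    cell <- nonzero_off[sample.int(length(nonzero_off), 1)]
    A[cell] <- 0
  } else {
    cell <- nonzero[sample.int(length(nonzero), 1)]
    A[cell] <- A[cell] * (1 + runif(1, -f, f))
  }
  out <- model
  out$A <- A
  list(model = out, move = move)
}

# Internal fitness: simulate the model from the course's first observed
# state and score with the gene-count-weighted correlation.
sa_fitness <- function(A, course, gene_counts) {
  .sim_fitness(A, course$times, course$observed, as.numeric(gene_counts))
}

#' One simulated-annealing run against an observed time course
#'
#' Per step a perturbation is proposed with [perturb_matrix()]; an
#' improving move is always accepted, a deleterious one is accepted with
#' probability `p_accept0 * (1 - cooling)^step`, otherwise rejected. The
#' best model seen so far is tracked and returned. The run is fully
#' reproducible from its seed.
#'
#' @param start an [influence_model()] starting point.
#' @param course a [time_course()] to calibrate against; its first
#'   observed state initializes every simulation.
#' @param config an [sa_config()].
#' @param p_accept0 initial deleterious-acceptance probability for this
#'   run (stage-dependent).
#' @param steps number of annealing steps (>= 0).
#' @param seed integer seed for this run.
#' @return An object of class `sa_run`: list with `seed`, `trace`
#'   (data.frame step / fitness / best), `best_model`, `best_fitness`.
#' @export
anneal_stage <- function(start, course, config, p_accept0, steps, seed = config$seed) {
  stopifnot(inherits(start, "influence_model"), inherits(course, "time_course"))
  if (steps < 0) stop("steps must be >= 0", call. = FALSE)
  set.seed(seed)
  current <- start
  f_cur <- sa_fitness(current$A, course, start$gene_counts)
  best <- current
  f_best <- f_cur
  trace_fit <- numeric(steps)
  trace_best <- numeric(steps)
  for (s in seq_len(steps)) {
    prop <- perturb_matrix(current, config)
    f_new <- sa_fitness(prop$model$A, course, start$gene_counts)
    accept <- if (f_new >= f_cur) TRUE else {
      runif(1) < p_accept0 * (1 - config$cooling)^s
    }
    if (accept) {
      current <- prop$model
      f_cur <- f_new
      if (f_new > f_best) {
        best <- prop$model
        f_best <- f_new
      }
    }
    trace_fit[s] <- f_cur
    trace_best[s] <- f_best
  }
  structure(list(seed = seed,
                 trace = data.frame(step = seq_len(steps), fitness = trace_fit,
                                    best = trace_best),
                 best_model = best, best_fitness = f_best,
                 start_fitness = sa_fitness(start$A, course, start$gene_counts)),
            class = "sa_run")
}

#' Two-stage simulated-annealing calibration
#'
#' Stage 1 performs `n_runs` independent annealing runs from the initial
#' model with a high deleterious-acceptance probability, exploring the
#' parameter space around the starting matrix. The best stage-1 model
#' seeds `n_runs` stage-2 runs with a low acceptance probability and more
#' steps, refining around the best solution. The final model is the best
#' stage-2 model (ties broken toward the lowest run index).
#'
#' @inheritParams anneal_stage
#' @return List with `stage1` and `stage2` ensembles (class `sa_ensemble`:
#'   `runs`, `stage`, `best_run`) and `best_model`, `best_fitness`.
#' @export
optimize_two_stage <- function(start, course, config) {
  run_stage <- function(init, p0, steps, stage) {
    runs <- lapply(seq_len(config$n_runs), function(r) {
      anneal_stage(init, course, config, p0, steps,
                   seed = derive_seed(config$seed, paste0("stage", stage, "/run", r)))
    })
    fits <- vapply(runs, `[[`, numeric(1), "best_fitness")
    structure(list(runs = runs, stage = stage, best_run = which.max(fits)),
              class = "sa_ensemble")
  }
  s1 <- run_stage(start, config$p_accept0_stage1, config$steps_stage1, 1L)
  best1 <- s1$runs[[s1$best_run]]$best_model
  s2 <- run_stage(best1, config$p_accept0_stage2, config$steps_stage2, 2L)
  best2 <- s2$runs[[s2$best_run]]
  list(stage1 = s1, stage2 = s2,
       best_model = best2$best_model, best_fitness = best2$best_fitness)
}

#' Collect the best models of an annealing ensemble
#'
#' @param ensemble an `sa_ensemble` from [optimize_two_stage()].
#' @return List of `influence_model`s, one per run.
#' @export
ensemble_models <- function(ensemble) {
  stopifnot(inherits(ensemble, "sa_ensemble"))
  lapply(ensemble$runs, `[[`, "best_model")
}
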