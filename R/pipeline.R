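# Allowed configuration schema: top-level keys and per-stage keys. An
# unknown key anywhere is a config error before any computation runs.
pipeline_schema <- list(
  seed = NULL, out_dir = NULL, stages = NULL,
  input = c("expression", "metadata", "annotations", "interactions",
            "synthetic"),
  synthetic = c("n_clusters", "edge_density", "gene_counts", "sigma_obs",
                "sigma_gene", "purity", "concordance", "treatments", "times"),
  filter = c("stats", "p_max", "fc_min"),
  cluster = c("divisions", "thresholds"),
  infer = c("min_support", "weight_floor", "tau"),
  optimize = c("treatments", "n_runs", "steps_stage1", "steps_stage2",
               "p_accept0_stage1", "p_accept0_stage2", "cooling",
               "perturb_range", "p_add", "p_remove"),
  nulltest = c("mode", "n_reps"),
  validate = c("n_reps", "alpha"),
  consensus = c("group_a", "group_b")
)

validate_config <- function(config) {
  unknown_top <- setdiff(names(config), names(pipeline_schema))
  if (length(unknown_top) > 0) {
    stop(sprintf("unknown config key '%s'", unknown_top[1]), call. = FALSE)
  }
  for (sec in intersect(names(config), names(pipeline_schema))) {
    allowed <- pipeline_schema[[sec]]
    if (is.null(allowed) || !is.list(config[[sec]])) next
    unknown <- setdiff(names(config[[sec]]), allowed)
    if (length(unknown) > 0) {
      stop(sprintf("unknown config key '%s.%s'", sec, unknown[1]), call. = FALSE)
    }
  }
  if (is.null(config$seed)) stop("config needs a `seed`", call. = FALSE)
  if (is.null(config$out_dir)) stop("config needs an `out_dir`", call. = FALSE)
  invisible(config)
}

default_stages <- c("cluster", "infer", "optimize", "nulltest", "validate",
                    "consensus")

#' Run the full modeling workflow from one configuration
#'
#' Executes the enabled stages in order — probe filter, module discovery,
#' steady-state inference, two-stage annealing calibration (one model per
#' selected treatment), randomization null test, interaction-set
#' validation, and group-consensus comparison — writing each stage's
#' artifacts (TSV/JSON) into `out_dir` plus a `manifest.json` with a
#' config echo and the MD5 hash of every artifact. All randomness derives
#' from the single global `seed`, so identical configs produce
#' byte-identical artifacts. Inputs come either from TSV paths under
#' `input:` or, when `input.synthetic` is set, from the bundled
#' synthetic-data generator.
#'
#' @param config a YAML file path or an equivalent nested list. Keys:
#'   `seed`, `out_dir`, `stages` (subset of cluster, infer, optimize,
#'   nulltest, validate, consensus), `input` (file paths or `synthetic:`
#'   generator parameters), and per-stage parameter blocks (`filter`,
#'   `cluster`, `infer`, `optimize`, `nulltest`, `validate`,
#'   `consensus`).
#' @return The manifest, invisibly (list with per-stage artifact paths
#'   and hashes).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  validate_config(config)
  seed <- as.integer(config$seed)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- config$stages %||% default_stages
  bad <- setdiff(stages, default_stages)
  if (length(bad) > 0) stop(sprintf("unknown stage '%s'", bad[1]), call. = FALSE)
  artifacts <- list()
  note <- function(stage, path) {
    artifacts[[stage]] <<- c(artifacts[[stage]], path)
  }

  # ---- inputs -------------------------------------------------------
  syn <- NULL
  if (!is.null(config$input$synthetic) || !is.null(config$synthetic)) {
    sp <- config$input$synthetic %||% config$synthetic
    truth_model <- generate_truth_model(
      n_clusters = sp$n_clusters %||% 10L,
      edge_density = sp$edge_density %||% 0.1,
      gene_counts = sp$gene_counts %||% 20L,
      seed = derive_seed(seed, "truth"))
    truth <- synthetic_truth(truth_model,
                             sigma_obs = sp$sigma_obs %||% 0.1,
                             sigma_gene = sp$sigma_gene %||% 0.3,
                             purity = sp$purity %||% 0.9,
                             concordance = sp$concordance %||% 0.9,
                             seed = derive_seed(seed, "synthetic"))
    syn <- generate_expression_dataset(
      truth,
      treatments = sp$treatments %||% c("lps", "cpg", "ip", "saline", "sham"),
      times = sp$times %||% c(3, 24, 72, 75, 96))
    vdata <- generate_validation_data(truth, syn$assignment)
    table <- syn$table
    annotations <- vdata$annotations
    interactions <- vdata$interactions
    expr_path <- file.path(out_dir, "expression.tsv")
    write_expression_table(table, expr_path, file.path(out_dir, "metadata.tsv"))
    note("input", expr_path)
  } else {
    if (is.null(config$input$expression)) {
      stop("dependency error: stage 'input' needs expression data or a synthetic block",
           call. = FALSE)
    }
    table <- read_expression_table(config$input$expression,
                                   config$input$metadata)
    annotations <- if (!is.null(config$input$annotations)) {
      read_annotation_tsv(config$input$annotations)
    }
    interactions <- if (!is.null(config$input$interactions)) {
      paths <- config$input$interactions
      setNames(lapply(paths, read_interaction_set), basename(unlist(paths)))
    }
  }

  # ---- filter (optional, needs probe statistics) --------------------
  if (!is.null(config$filter$stats)) {
    stats_df <- read.delim(config$filter$stats)
    kept <- filter_probes(stats_df,
                          p_max = config$filter$p_max %||% 0.05,
                          fc_min = config$filter$fc_min %||% 2.0)
    table$values <- table$values[rownames(table$values) %in% kept, , drop = FALSE]
    writeLines(kept, file.path(out_dir, "kept_genes.txt"))
    note("filter", file.path(out_dir, "kept_genes.txt"))
  }

  # ---- cluster ------------------------------------------------------
  if ("cluster" %in% stages) {
    divisions <- config$cluster$divisions %||% seq(5, 50, by = 5)
    divisions <- divisions[divisions <= nrow(table$values)]
    assignments <- build_tree_and_cut(table, divisions)
    if (!is.null(annotations)) {
      curve <- coherence_curve(assignments, annotations,
                               thresholds = config$cluster$thresholds %||%
                                 c(0.05, 0.01, 0.001))
      best_K <- curve$best_division[1]
      curve_path <- file.path(out_dir, "coherence_curve.tsv")
      write.table(data.frame(division = curve$divisions, curve$scores,
                             check.names = FALSE),
                  curve_path, sep = "\t", quote = FALSE, row.names = FALSE)
      note("cluster", curve_path)
    } else {
      best_K <- max(divisions)
    }
    assignment <- assignments[[as.character(best_K)]]
    assign_path <- file.path(out_dir, "clusters.tsv")
    write.table(data.frame(gene_id = names(assignment), cluster = assignment),
                assign_path, sep = "\t", quote = FALSE, row.names = FALSE)
    note("cluster", assign_path)
  } else if (!is.null(syn)) {
    assignment <- syn$assignment
  } else {
    stop("dependency error: stage 'infer' requires stage 'cluster'", call. = FALSE)
  }
  profiles <- cluster_mean_profiles(table, assignment)
  courses <- profiles_to_courses(profiles)

  # ---- infer --------------------------------------------------------
  model0 <- NULL
  if ("infer" %in% stages) {
    folds <- infer_cv_models(profiles)
    report <- consensus_initial_model(
      folds,
      min_support = config$infer$min_support %||% 3,
      weight_floor = config$infer$weight_floor %||% 0.1)
    tau0 <- rep(config$infer$tau %||% 20, nrow(report$consensus))
    model0 <- build_influence_model(report$consensus, tau0,
                                    profiles$gene_counts,
                                    cluster_ids = profiles$cluster_ids)
    model_path <- file.path(out_dir, "model0.tsv")
    write_model_tsv(model0, model_path)
    jsonlite::write_json(
      list(mean_performance = report$mean_performance,
           per_treatment = as.list(report$per_treatment_performance)),
      file.path(out_dir, "model0.json"), auto_unbox = TRUE, digits = NA)
    note("infer", model_path)
    note("infer", file.path(out_dir, "model0.json"))
  }

  # ---- optimize -----------------------------------------------------
  best_models <- list()
  if ("optimize" %in% stages) {
    if (is.null(model0)) {
      stop("dependency error: stage 'optimize' requires stage 'infer'",
           call. = FALSE)
    }
    oc <- config$optimize
    sac <- sa_config(n_runs = oc$n_runs %||% 25,
                     steps_stage1 = oc$steps_stage1 %||% 5000,
                     steps_stage2 = oc$steps_stage2 %||% 25000,
                     p_accept0_stage1 = oc$p_accept0_stage1 %||% 0.80,
                     p_accept0_stage2 = oc$p_accept0_stage2 %||% 0.10,
                     cooling = oc$cooling %||% 0.002,
                     perturb_range = oc$perturb_range %||% 0.6,
                     p_add = oc$p_add %||% 0.001,
                     p_remove = oc$p_remove %||% 0.01,
                     seed = seed)
    opt_treatments <- oc$treatments %||% names(courses)
    for (tr in opt_treatments) {
      sac_tr <- sac
      sac_tr$seed <- derive_seed(seed, paste0("optimize/", tr))
      res <- optimize_two_stage(model0, courses[[tr]], sac_tr)
      best_models[[tr]] <- res$best_model
      path <- file.path(out_dir, sprintf("model_%s.tsv", tr))
      write_model_tsv(res$best_model, path)
      note("optimize", path)
      trace <- res$stage2$runs[[res$stage2$best_run]]$trace
      tr_path <- file.path(out_dir, sprintf("trace_%s.tsv", tr))
      write.table(trace, tr_path, sep = "\t", quote = FALSE, row.names = FALSE)
      note("optimize", tr_path)
    }
  }

  # ---- nulltest -----------------------------------------------------
  if ("nulltest" %in% stages) {
    if (length(best_models) == 0) {
      stop("dependency error: stage 'nulltest' requires stage 'optimize'",
           call. = FALSE)
    }
    tr <- names(best_models)[1]
    nr <- significance_test(best_models[[tr]], courses[[tr]],
                            mode = config$nulltest$mode %||% "scramble",
                            n_reps = config$nulltest$n_reps %||% 100,
                            seed = derive_seed(seed, "nulltest"))
    null_path <- file.path(out_dir, "nulltest.json")
    jsonlite::write_json(
      nr[c("mode", "n_reps", "observed", "empirical_p", "parametric_p",
           "null_mean", "null_sd")],
      null_path, auto_unbox = TRUE, digits = NA, na = "null")
    note("nulltest", null_path)
  }

  # ---- validate -----------------------------------------------------
  if ("validate" %in% stages) {
    if (length(best_models) == 0 || is.null(interactions)) {
      stop("dependency error: stage 'validate' requires stage 'optimize' and interaction sets",
           call. = FALSE)
    }
    pv <- lapply(seq_along(interactions), function(j) {
      rewire_pvalues(assignment, interactions[[j]],
                     n_reps = config$validate$n_reps %||% 1000,
                     seed = derive_seed(seed, paste0("validate/", j)))
    })
    names(pv) <- names(interactions)
    vt <- validation_accuracy(best_models[[1]], pv,
                              alpha = config$validate$alpha %||% 0.05)
    val_path <- file.path(out_dir, "validation.tsv")
    write.table(vt$pairs, val_path, sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(accuracy = as.list(vt$accuracy), any_accuracy = vt$any_accuracy),
      file.path(out_dir, "validation.json"), auto_unbox = TRUE, digits = NA)
    note("validate", val_path)
    note("validate", file.path(out_dir, "validation.json"))
  }

  # ---- consensus ----------------------------------------------------
  if ("consensus" %in% stages) {
    ga <- config$consensus$group_a
    gb <- config$consensus$group_b
    if (is.null(ga) || is.null(gb) ||
        !all(c(unlist(ga), unlist(gb)) %in% names(best_models))) {
      stop("dependency error: stage 'consensus' needs optimized models for both groups",
           call. = FALSE)
    }
    ca <- group_consensus(best_models[unlist(ga)], label = "group_a")
    cb <- group_consensus(best_models[unlist(gb)], label = "group_b")
    cmp <- compare_groups(ca, cb)
    cmp_path <- file.path(out_dir, "edge_status.tsv")
    write.table(cmp, cmp_path, sep = "\t", quote = FALSE, row.names = FALSE)
    note("consensus", cmp_path)
  }

  # ---- manifest -----------------------------------------------------
  paths <- unlist(artifacts, use.names = FALSE)
  manifest <- list(
    config = config,
    stages_run = stages,
    artifacts = artifacts,
    hashes = as.list(setNames(unname(tools::md5sum(paths)), basename(paths)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

# Observed time courses per treatment from a cluster profile matrix.
profiles_to_courses <- function(profiles) {
  meta <- profiles$samples
  out <- lapply(unique(meta$treatment), function(tr) {
    cols <- which(meta$treatment == tr)
    cols <- cols[order(meta$time_h[cols])]
    time_course(tr, meta$time_h[cols],
                profiles$values[, cols, drop = FALSE],
                cluster_ids = profiles$cluster_ids)
  })
  names(out) <- unique(meta$treatment)
  out
}

#' Read a gene annotation table (columns `gene_id`, `term_id`)
#'
#' @param path TSV path, one (gene, term) pair per line.
#' @return Named list mapping gene id to character vector of term ids.
#' @export
read_annotation_tsv <- function(path) {
  df <- read.delim(path, colClasses = "character")
  split(df$term_id, df$gene_id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
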