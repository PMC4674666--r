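# Orchestration: simulate -> measure (geometry + dissimilarity) ->
# analyze, as one reproducible, seeded run.

#' Bundle all run parameters
#'
#' @param generator a [generator_config()].
#' @param behavior a [behavior_config()].
#' @param alpha backward-elimination retention threshold.
#' @param tolerance_px dissimilarity match tolerance in pixels.
#' @param fisher_reps Monte Carlo replicates for the Fisher test.
#' @param seed master seed; per-stage seeds are derived from it
#'   deterministically (see [stage_seed()]).
#' @param outdir optional output directory; when non-NULL,
#'   [run_experiment()] writes annotations, change scores, outcomes, model
#'   tables and a summary there.
#' @return an object of class `run_config`.
#' @export
run_config <- function(generator = generator_config(),
                       behavior = behavior_config(),
                       alpha = 0.05, tolerance_px = 2, fisher_reps = 1e5,
                       seed = 1, outdir = NULL) {
  stopifnot(inherits(generator, "generator_config"),
            inherits(behavior, "behavior_config"),
            alpha > 0, alpha <= 1, tolerance_px >= 0, fisher_reps >= 1)
  structure(list(generator = generator, behavior = behavior, alpha = alpha,
                 tolerance_px = tolerance_px, fisher_reps = fisher_reps,
                 seed = as.integer(seed), outdir = outdir),
            class = "run_config")
}

#' Derive a per-stage seed from the master seed
#'
#' `(master * 48271 + stage * 1000003) mod (2^31 - 1)`: distinct small
#' stages give distinct, reproducible 31-bit seeds, so any stage can be
#' rerun in isolation.
#'
#' @param master master seed (integer).
#' @param stage stage index (integer).
#' @return integer seed.
#' @export
stage_seed <- function(master, stage) {
  as.integer((as.numeric(master) %% 2147483647 * 48271 +
                as.numeric(stage) * 1000003) %% 2147483647)
}

#' Serialize / restore a run configuration
#'
#' @param config a [run_config()].
#' @param path JSON file path.
#' @return `write_run_config`: `path`, invisibly. `read_run_config`: a
#'   [run_config()] identical (for rerun purposes) to the one written.
#' @export
write_run_config <- function(config, path) {
  # named vectors become JSON objects (lists) so names survive the round trip
  listify <- function(cfg) lapply(unclass(cfg), function(v)
    if (!is.null(names(v))) as.list(v) else v)
  x <- list(generator = listify(config$generator),
            behavior = listify(config$behavior),
            alpha = config$alpha, tolerance_px = config$tolerance_px,
            fisher_reps = config$fisher_reps, seed = config$seed)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  gen <- do.call(generator_config, lapply(x$generator, unlist))
  beh <- do.call(behavior_config, x$behavior)
  run_config(generator = gen, behavior = beh, alpha = x$alpha,
             tolerance_px = x$tolerance_px, fisher_reps = x$fisher_reps,
             seed = x$seed)
}

#' Simulate and measure one nest
#'
#' Generates a before clutch, applies the treatment, and scores the change:
#' the four arrangement SDs plus the mask dissimilarity.
#'
#' @param treatment treatment label.
#' @param clutch_size number of host eggs.
#' @param nest_id nest identifier.
#' @param config a [run_config()].
#' @param seed integer seed for this nest.
#' @return list with `before`, `after` (observations) and `scores` (one-row
#'   data.frame: change SDs + `dissimilarity`).
#' @export
measure_nest <- function(treatment, clutch_size, nest_id, config = run_config(),
                         seed = 1) {
  gen <- config$generator
  before <- generate_clutch(gen, clutch_size, nest_id, seed = seed)
  after <- apply_treatment(before, treatment, gen,
                           seed = stage_seed(seed, 7))
  scores <- arrangement_change(before, after)
  d <- mask_dissimilarity(render_mask(before, gen), render_mask(after, gen),
                          tolerance_px = config$tolerance_px)
  scores$dissimilarity <- d$value
  scores$treatment <- treatment
  scores$clutch_size <- clutch_size
  list(before = before, after = after, scores = scores)
}

#' Run the full simulated experiment
#'
#' Simulates all nests of the three-treatment design, measures arrangement
#' change and mask dissimilarity per nest, simulates behavioral outcomes,
#' and runs the statistical stage: per-group desertion/ejection rates, a
#' Fisher exact test (enumeration + Monte Carlo) of desertion in control
#' vs parasitized nests, and backward-eliminated binomial (ejection) and
#' negative-binomial (latency) models. Fully deterministic given the
#' master seed. When `config$outdir` is set, all tables are written there
#' as CSV plus a JSON config snapshot.
#'
#' @param config a [run_config()].
#' @return an object of class `egg_experiment`: list with `assignments`,
#'   `scores`, `group_means`, `outcomes`, `rates`, `fisher`,
#'   `response_model`, `latency_model`, `config`.
#' @export
run_experiment <- function(config = run_config()) {
  gen <- config$generator
  if (any(gen$n_nests < 1))
    stop("configuration error: every treatment group needs at least one nest")
  groups <- c("control", "constant", "rearranged")

  set.seed(stage_seed(config$seed, 1))
  assignments <- data.frame(
    nest_id = paste0("nest", seq_len(sum(gen$n_nests[groups]))),
    treatment = rep(groups, times = gen$n_nests[groups]))
  assignments$clutch_size <- draw_clutch_sizes(nrow(assignments), gen)

  observations <- vector("list", 2 * nrow(assignments))
  scores <- vector("list", nrow(assignments))
  for (i in seq_len(nrow(assignments))) {
    m <- measure_nest(assignments$treatment[i], assignments$clutch_size[i],
                      assignments$nest_id[i], config,
                      seed = stage_seed(config$seed, 100 + i))
    observations[[2 * i - 1]] <- m$before
    observations[[2 * i]] <- m$after
    scores[[i]] <- m$scores
  }
  scores <- do.call(rbind, scores)

  metric_cols <- c("sd_blunt_pole_distance", "sd_blunt_pole_angle",
                   "sd_blunt_pole_orientation", "sd_adjacent_angle",
                   "dissimilarity")
  group_means <- do.call(rbind, lapply(groups, function(g) {
    sub <- scores[scores$treatment == g, metric_cols, drop = FALSE]
    cbind(data.frame(treatment = g, n = nrow(sub)),
          as.data.frame(lapply(sub, mean)),
          stats::setNames(as.data.frame(lapply(sub, stats::sd)),
                          paste0("sd_of_", metric_cols)))
  }))

  outcomes <- simulate_outcomes(assignments, config$behavior,
                                seed = stage_seed(config$seed, 2))
  rates <- proportion_summary(outcomes)

  deserted <- outcomes$response == "desert"
  parasitized <- outcomes$treatment != "control"
  fisher_tab <- matrix(c(sum(deserted & !parasitized), sum(!deserted & !parasitized),
                         sum(deserted & parasitized), sum(!deserted & parasitized)),
                       2, 2, byrow = TRUE,
                       dimnames = list(c("control", "parasitized"),
                                       c("deserted", "not_deserted")))
  fisher <- fisher_exact(fisher_tab, n_reps = config$fisher_reps,
                         seed = stage_seed(config$seed, 3))

  response_model <- backward_eliminate(outcomes, "response", alpha = config$alpha)
  latency_model <- backward_eliminate(outcomes, "latency", alpha = config$alpha)

  report <- structure(
    list(assignments = assignments, scores = scores, group_means = group_means,
         outcomes = outcomes, rates = rates, fisher = fisher,
         response_model = response_model, latency_model = latency_model,
         config = config),
    class = "egg_experiment")

  if (!is.null(config$outdir)) {
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    out <- function(f) file.path(config$outdir, f)
    write_annotations(observations, out("annotations.csv"))
    utils::write.csv(scores, out("change_scores.csv"), row.names = FALSE)
    utils::write.csv(group_means, out("group_means.csv"), row.names = FALSE)
    utils::write.csv(outcomes, out("outcomes.csv"), row.names = FALSE)
    utils::write.csv(rates, out("rates.csv"), row.names = FALSE)
    utils::write.csv(model_table(report), out("model_tables.csv"), row.names = FALSE)
    write_run_config(config, out("config.json"))
    writeLines(utils::capture.output(print(report)), out("report.txt"))
  }
  report
}

model_table <- function(report) {
  one <- function(res, model, which) {
    tt <- res$terms
    tt$model <- model; tt$panel <- which
    tt$pseudo_r2 <- res$pseudo_r2; tt$family <- res$family
    tt
  }
  rbind(one(report$response_model$full, "response", "full"),
        one(report$response_model$final, "response", "final"),
        one(report$latency_model$full, "latency", "full"),
        one(report$latency_model$final, "latency", "final"))
}

#' @export
print.egg_experiment <- function(x, ...) {
  cat("== Simulated egg-arrangement experiment ==\n\n")
  cat("Arrangement change (group means):\n")
  gm <- x$group_means
  gm[-1] <- lapply(gm[-1], function(col) round(col, 3))
  print(gm[, 1:7], row.names = FALSE)
  cat("\nBehavioral rates:\n")
  r <- x$rates
  r$desertion_pct <- round(r$desertion_pct, 1)
  r$ejection_pct <- round(r$ejection_pct, 1)
  print(r, row.names = FALSE)
  cat("\nDesertion, control vs parasitized: ")
  print(x$fisher)
  cat("\nResponse model (final):\n")
  print(x$response_model$final)
  cat("\nLatency model (final):\n")
  print(x$latency_model$final)
  invisible(x)
}

#' Recompute the published outcome percentages and Fisher test
#'
#' Rebuilds the field experiment's outcome table from its printed counts
#' (19/30/30 nests; 2, 5 and 3 desertions; 19 of 24 and 24 of 27
#' ejections in the constant and rearranged groups -- one constant nest
#' had no definitive outcome) and recomputes the five percentages and the
#' exact test of desertion against treatment from it.
#'
#' @param fisher_reps Monte Carlo replicates for the Fisher test.
#' @param seed seed for the Monte Carlo draw.
#' @return list with `rates` (from [proportion_summary()]), `fisher`
#'   (from [fisher_exact()] on the 2x2 desertion table) and `outcomes`
#'   (the reconstructed table).
#' @export
reproduce_printed_results <- function(fisher_reps = 1e5, seed = 1) {
  counts <- list(
    control = c(desert = 2, eject = 0, accept = 17, unknown = 0),
    constant = c(desert = 5, eject = 19, accept = 5, unknown = 1),
    rearranged = c(desert = 3, eject = 24, accept = 3, unknown = 0))
  outcomes <- do.call(rbind, lapply(names(counts), function(g) {
    k <- counts[[g]]
    data.frame(treatment = g,
               response = c(rep("desert", k["desert"]), rep("eject", k["eject"]),
                            rep("accept", k["accept"]), rep(NA, k["unknown"])))
  }))
  deserted <- !is.na(outcomes$response) & outcomes$response == "desert"
  parasitized <- outcomes$treatment != "control"
  tab <- matrix(c(sum(deserted & !parasitized), sum(!deserted & !parasitized),
                  sum(deserted & parasitized), sum(!deserted & parasitized)),
                2, 2, byrow = TRUE,
                dimnames = list(c("control", "parasitized"),
                                c("deserted", "not_deserted")))
  list(rates = proportion_summary(outcomes),
       fisher = fisher_exact(tab, n_reps = fisher_reps, seed = seed),
       outcomes = outcomes)
}
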