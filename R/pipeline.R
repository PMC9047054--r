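# File interchange and end-to-end orchestration. CSV is the interchange
# format throughout: block-aggregated EHR features have no clinical standard
# container, and CSV keeps every artifact diffable and reproducible.

#' Read a raw records CSV
#'
#' Expects columns `patient_id`, `block_time_hours`, `feature`, `value`.
#' Unknown extra columns are ignored with a warning; missing required columns
#' or non-numeric values in numeric fields are errors naming the offender.
#'
#' @param path CSV path.
#' @return Validated records data.frame.
#' @export
read_records <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("empty records file: ", path, call. = FALSE)
  required <- c("patient_id", "block_time_hours", "feature", "value")
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop("records file is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(df), required)
  if (length(extra)) {
    warning("ignoring unknown column(s): ", paste(extra, collapse = ", "),
            call. = FALSE)
  }
  df <- df[required]
  for (col in c("block_time_hours", "value")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]) & df[[col]] != "NA")
    if (length(bad)) {
      stop("non-numeric value in column ", col, " at data line(s) ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    }
    df[[col]] <- v
  }
  validate_records(df)
  df
}

#' Read an outcomes CSV
#'
#' @param path CSV with columns `patient_id`, `outcome` (1 = died).
#' @return Validated outcomes data.frame.
#' @export
read_outcomes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("empty outcomes file: ", path, call. = FALSE)
  miss <- setdiff(c("patient_id", "outcome"), names(df))
  if (length(miss)) {
    stop("outcomes file is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (!all(df$outcome %in% c(0, 1))) {
    stop("outcome must be 0 (survived) or 1 (died)", call. = FALSE)
  }
  df[c("patient_id", "outcome")]
}

#' Write a block table CSV
#'
#' Emits one row per block with a stable column order: `patient_id`, `bloc`,
#' the 25 state features, `balance`, and any of `action`, `reward`,
#' `terminal` that are present.
#'
#' @param path Output path.
#' @param blocks Block table.
#' @return `path`, invisibly.
#' @export
write_blocks <- function(path, blocks) {
  cols <- c("patient_id", "bloc", setdiff(state_features(), "bloc"), "balance",
            intersect(c("action", "reward", "terminal"), names(blocks)))
  utils::write.csv(blocks[, cols, drop = FALSE], path, row.names = FALSE)
  invisible(path)
}

#' Read a block table CSV written by [write_blocks()]
#'
#' @param path CSV path.
#' @return Block data.frame.
#' @export
read_blocks <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("patient_id", "bloc", state_features(), "balance"),
                  names(df))
  if (length(miss)) {
    stop("blocks file is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' Write a generated cohort to a directory
#'
#' Records and outcomes go to the directory root; the generative ground
#' truth is kept apart under `truth/` so no modeling stage reads it by
#' accident.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "truth"), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$records, file.path(dir, "records.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$outcomes, file.path(dir, "outcomes.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$truth$blocks, file.path(dir, "truth", "blocks.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$truth$patients,
                   file.path(dir, "truth", "patients.csv"), row.names = FALSE)
  invisible(dir)
}

#' Full preprocessing: raw records to train/test MDP datasets
#'
#' Runs the clinical preprocessing end to end: outlier rules, 6-hour block
#' aggregation, patient-level 8:2 split, imputation (forward-fill for labs,
#' KNN for the rest, training-median fallback; test data reuse the training
#' medians), quintile action bins fitted on training balances only, reward
#' assignment and transition construction.
#'
#' @param records Raw records table (or path via [read_records()]).
#' @param outcomes Outcomes table.
#' @param ratio Training fraction (default 0.8).
#' @param seed Split seed.
#' @param k KNN neighbours (default 5).
#' @param block_hours,max_blocks Block aggregation parameters.
#' @return List of class `mdp_dataset`: `train_blocks`, `test_blocks`,
#'   `bins`, `medians`, `split`, `exclusions`, `train_transitions`,
#'   `test_transitions`.
#' @export
preprocess_cohort <- function(records, outcomes, ratio = 0.8, seed = 1L,
                              k = 5L, block_hours = 6, max_blocks = 18L) {
  cleaned <- apply_outlier_rules(records, outcomes)
  blocks <- segment_blocks(cleaned$records, block_hours = block_hours,
                           max_blocks = max_blocks)
  split <- split_patients(unique(blocks$patient_id), ratio = ratio,
                          seed = seed)
  train <- blocks[blocks$patient_id %in% split$train, , drop = FALSE]
  test <- blocks[blocks$patient_id %in% split$test, , drop = FALSE]
  train <- impute_missing(train, k = k)
  medians <- attr(train, "medians")
  test <- impute_missing(test, k = k, medians = medians)
  bins <- fit_action_bins(train$balance)
  train$action <- discretize_balance(train$balance, bins)
  test$action <- discretize_balance(test$balance, bins)
  train <- assign_rewards(train, outcomes)
  test <- assign_rewards(test, outcomes)
  structure(list(
    train_blocks = train, test_blocks = test, bins = bins,
    medians = medians, split = split, exclusions = cleaned$exclusions,
    train_transitions = build_transitions(train),
    test_transitions = build_transitions(test)
  ), class = "mdp_dataset")
}

#' Pipeline configuration
#'
#' Bundles every stage's options for [run_pipeline()].
#'
#' @param cohort A [cohort_config()] (the simulated input cohort).
#' @param workdir Directory receiving all artifacts.
#' @param split_ratio,split_seed Patient split options.
#' @param k_neighbors KNN imputation neighbours.
#' @param block_hours,max_blocks Block aggregation options.
#' @param sarsa,ddqn [training_config()]s for the two learners.
#' @param ope_clip Propensity floor.
#' @param ope_min_consistent Minimum consistent samples for the outcome
#'   model (default 30).
#' @param gamma_attr Reward-attribution discount.
#' @param n_bins Bins for the mortality curves.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort, workdir,
                            split_ratio = 0.8, split_seed = 1L,
                            k_neighbors = 5L, block_hours = 6,
                            max_blocks = 18L,
                            sarsa = training_config(iterations = 2000,
                                                    target_clip = c(-15, 15),
                                                    weight_decay = 1e-4),
                            ddqn = training_config(
                              iterations = 30000,
                              checkpoint_iterations = c(3000, 10000, 20000,
                                                        30000),
                              target_clip = c(-15, 15),
                              weight_decay = 1e-4),
                            ope_clip = 0.01, ope_min_consistent = 30L,
                            gamma_attr = 0.99,
                            n_bins = 10L) {
  structure(list(cohort = cohort, workdir = workdir,
                 split_ratio = split_ratio, split_seed = split_seed,
                 k_neighbors = k_neighbors, block_hours = block_hours,
                 max_blocks = max_blocks, sarsa = sarsa, ddqn = ddqn,
                 ope_clip = ope_clip,
                 ope_min_consistent = as.integer(ope_min_consistent),
                 gamma_attr = gamma_attr,
                 n_bins = n_bins),
            class = "pipeline_config")
}

# Polynomial rolling hash (mod 2^31 - 1) of the serialized configuration;
# stamps run artifacts.
config_hash <- function(config) {
  s <- jsonlite::toJSON(unclass_deep(config), auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(s))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

unclass_deep <- function(x) {
  if (is.list(x)) return(lapply(unclass(x), unclass_deep))
  if (is.function(x)) return(NULL)
  unclass(x)
}

#' Run the full pipeline
#'
#' Executes simulate -> preprocess -> train-sarsa -> train-ddqn -> evaluate
#' -> report, writing every artifact under the configured work directory.
#' Reruns with the same configuration reproduce identical CSV outputs. A
#' failing stage aborts with the stage named; artifacts of completed stages
#' are retained.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory artifacts (`cohort`, `mdp`,
#'   `sarsa`, `ddqn`, `ope_report`, `analysis`) and `workdir`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    stop("config must be a pipeline_config", call. = FALSE)
  }
  wd <- config$workdir
  dir.create(wd, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  meta <- list(config_hash = config_hash(config),
               seed = config$cohort$seed,
               stages = c("simulate", "preprocess", "train-sarsa",
                          "train-ddqn", "evaluate", "report"))
  jsonlite::write_json(meta, file.path(wd, "run_metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  cohort <- stage("simulate", {
    co <- generate_cohort(config$cohort)
    write_cohort(co, wd)
    co
  })
  mdp <- stage("preprocess", {
    m <- preprocess_cohort(cohort$records, cohort$outcomes,
                           ratio = config$split_ratio,
                           seed = config$split_seed,
                           k = config$k_neighbors,
                           block_hours = config$block_hours,
                           max_blocks = config$max_blocks)
    write_blocks(file.path(wd, "blocks_train.csv"), m$train_blocks)
    write_blocks(file.path(wd, "blocks_test.csv"), m$test_blocks)
    jsonlite::write_json(
      list(action_bin_edges = m$bins$edges,
           imputation_medians = as.list(m$medians),
           n_train_patients = length(m$split$train),
           n_test_patients = length(m$split$test),
           n_excluded_records = nrow(m$exclusions),
           exclusions_by_rule = as.list(table(m$exclusions$rule))),
      file.path(wd, "preprocess_meta.json"), auto_unbox = TRUE, pretty = TRUE)
    utils::write.csv(check_split_balance(m$train_blocks, m$test_blocks),
                     file.path(wd, "split_balance.csv"), row.names = FALSE)
    m
  })
  sarsa <- stage("train-sarsa", {
    m <- train_sarsa(mdp$train_transitions, config$sarsa)
    dir.create(file.path(wd, "models"), showWarnings = FALSE)
    write_model(m, file.path(wd, "models", "sarsa.json"))
    m
  })
  ddqn <- stage("train-ddqn", {
    m <- train_ddqn(mdp$train_transitions, config$ddqn)
    write_model(m, file.path(wd, "models", "ddqn.json"))
    m
  })
  ope_report <- stage("evaluate", {
    prop <- fit_propensities(mdp$train_blocks, clip = config$ope_clip)
    ddqn_eval <- if (length(ddqn$checkpoints)) ddqn else {
      ddqn$checkpoints <- stats::setNames(list(ddqn$q),
                                          as.character(ddqn$config$iterations))
      ddqn
    }
    rep <- evaluate_checkpoints(ddqn_eval, mdp$test_blocks, prop,
                                gamma_attr = config$gamma_attr,
                                min_consistent = config$ope_min_consistent)
    utils::write.csv(rep, file.path(wd, "ope_report.csv"), row.names = FALSE)
    rep
  })
  analysis <- stage("report", {
    test <- mdp$test_blocks
    died <- cohort$outcomes$outcome[match(test$patient_id,
                                          cohort$outcomes$patient_id)]
    states <- as.matrix(test[, state_features(), drop = FALSE])
    ai_actions <- predict_actions(ddqn, states)
    reps <- bin_median_balance(mdp$train_blocks$balance, mdp$bins)
    mr <- mortality_by_expected_reward(sarsa, test, cohort$outcomes,
                                       n_bins = config$n_bins)
    bd <- balance_difference_mortality(ai_actions, test$balance, died, reps,
                                       n_bins = config$n_bins)
    cc <- concordance_mortality(binarize_actions(ai_actions),
                                binarize_actions(test$action), died)
    ad <- rbind(cbind(policy = "clinical", action_distribution(test$action)),
                cbind(policy = "ai", action_distribution(ai_actions)))
    utils::write.csv(mr, file.path(wd, "mortality_by_reward.csv"),
                     row.names = FALSE)
    utils::write.csv(bd, file.path(wd, "balance_difference_mortality.csv"),
                     row.names = FALSE)
    utils::write.csv(cc, file.path(wd, "concordance.csv"), row.names = FALSE)
    utils::write.csv(ad, file.path(wd, "action_distribution.csv"),
                     row.names = FALSE)
    list(mortality_by_reward = mr, balance_difference = bd,
         concordance = cc, action_distribution = ad,
         representatives = reps)
  })
  invisible(list(cohort = cohort, mdp = mdp, sarsa = sarsa, ddqn = ddqn,
                 ope_report = ope_report, analysis = analysis,
                 workdir = wd))
}
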