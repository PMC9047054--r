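#' Apply the per-feature outlier rules
#'
#' Cleans a raw records table with the fixed clinical rule set: clamping for
#' low inspired-oxygen concentration, record exclusion for out-of-range vitals,
#' blood-gas values and fluid volumes, and exclusion of zero vital signs in
#' patients who did not die. Exclusions operate on the offending record only,
#' never the whole patient.
#'
#' @param records data.frame with columns `patient_id`, `block_time_hours`,
#'   `feature`, `value`.
#' @param outcomes data.frame with `patient_id` and `outcome` (1 = died);
#'   required by the "value is 0 but not dead" rules.
#' @return List with `records` (cleaned table) and `exclusions` (data.frame of
#'   excluded records with the rule id that fired).
#' @examples
#' recs <- data.frame(patient_id = 1, block_time_hours = 0,
#'                    feature = "o2_concentration", value = 15)
#' out <- data.frame(patient_id = 1, outcome = 0)
#' apply_outlier_rules(recs, out)$records$value  # clamped to 21
#' @export
apply_outlier_rules <- function(records, outcomes) {
  validate_records(records)
  unknown <- setdiff(unique(records$feature), record_features())
  if (length(unknown)) {
    stop("unknown feature name(s) in records: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  dead_ids <- outcomes$patient_id[outcomes$outcome == 1]
  dead <- records$patient_id %in% dead_ids
  drop <- rep(FALSE, nrow(records))
  rule_hit <- rep(NA_character_, nrow(records))
  for (rule in outlier_rule_list()) {
    idx <- records$feature == rule$feature
    if (!any(idx)) next
    fired <- idx & rule$test(records$value, dead)
    if (rule$type == "clamp") {
      records$value[fired] <- rule$value
    } else {
      new_hit <- fired & !drop
      drop[new_hit] <- TRUE
      rule_hit[new_hit] <- rule$id
    }
  }
  exclusions <- records[drop, , drop = FALSE]
  exclusions$rule <- rule_hit[drop]
  rownames(exclusions) <- NULL
  cleaned <- records[!drop, , drop = FALSE]
  rownames(cleaned) <- NULL
  list(records = cleaned, exclusions = exclusions)
}

#' Aggregate records into 6-hour blocks
#'
#' Segments each patient's stay into consecutive 6-hour windows from
#' admission, averages each feature's records within a window, computes the
#' per-block fluid balance as mean(fluid_input) - mean(fluid_output)
#' (negative = net removal), and truncates stays at `max_blocks` windows
#' (108 h at the defaults). A patient's last block is their last window with
#' any record. Blocks with no computable balance are dropped (the fluid-volume
#' exclusion rules may remove a block's volumes); features never observed in a
#' window are left `NA` for [impute_missing()].
#'
#' @param records Cleaned records for one or more patients.
#' @param block_hours Window length in hours (default 6).
#' @param max_blocks Maximum windows per patient (default 18).
#' @return data.frame with `patient_id`, `bloc`, the 25 state-feature columns
#'   and `balance`.
#' @export
segment_blocks <- function(records, block_hours = 6, max_blocks = 18L) {
  validate_records(records)
  if (nrow(records) == 0) stop("empty record set", call. = FALSE)
  bloc <- floor(records$block_time_hours / block_hours) + 1L
  keep <- bloc <= max_blocks
  records <- records[keep, , drop = FALSE]
  bloc <- bloc[keep]
  if (nrow(records) == 0) stop("no records within the block horizon", call. = FALSE)
  key <- paste(records$patient_id, bloc, records$feature, sep = "\r")
  agg <- tapply(records$value, key, mean)
  parts <- strsplit(names(agg), "\r", fixed = TRUE)
  pid <- vapply(parts, `[`, "", 1L)
  if (!anyNA(suppressWarnings(as.integer(unique(pid))))) pid <- as.integer(pid)
  adf <- data.frame(
    patient_id = pid,
    bloc = as.integer(vapply(parts, `[`, "", 2L)),
    feature = vapply(parts, `[`, "", 3L),
    value = as.numeric(agg)
  )
  cells <- unique(adf[, c("patient_id", "bloc")])
  cells <- cells[order(cells$patient_id, cells$bloc), , drop = FALSE]
  feats <- c(setdiff(state_features(), "bloc"), "fluid_input", "fluid_output")
  wide <- matrix(NA_real_, nrow(cells), length(feats),
                 dimnames = list(NULL, feats))
  row_of <- stats::setNames(seq_len(nrow(cells)),
                            paste(cells$patient_id, cells$bloc))
  ij <- cbind(row_of[paste(adf$patient_id, adf$bloc)],
              match(adf$feature, feats))
  wide[ij] <- adf$value
  blocks <- data.frame(patient_id = cells$patient_id, bloc = cells$bloc)
  blocks <- cbind(blocks, as.data.frame(wide))
  blocks$balance <- blocks$fluid_input - blocks$fluid_output
  blocks$fluid_input <- NULL
  blocks$fluid_output <- NULL
  blocks <- blocks[!is.na(blocks$balance), , drop = FALSE]
  if (nrow(blocks) == 0) stop("no blocks with a computable fluid balance", call. = FALSE)
  # column order: patient_id, bloc, 23 measured state features, balance
  blocks <- blocks[, c("patient_id", "bloc", setdiff(state_features(), "bloc"),
                       "balance")]
  rownames(blocks) <- NULL
  blocks
}

# Pairwise squared distances between query rows and all rows over co-observed
# standardized dimensions; NA where no dimension is co-observed.
co_observed_dist2 <- function(Xq, Mq, X0, M) {
  A <- (Xq^2 * Mq) %*% t(M)
  B <- Mq %*% t(X0^2 * M)
  C <- (Xq * Mq) %*% t(X0 * M)
  N <- Mq %*% t(M)
  D <- (A + B - 2 * C) / N
  D[N == 0] <- NA_real_
  D
}

#' Impute missing block features
#'
#' Laboratory features are forward-filled within each patient (labs are
#' measured sparsely, so the last observation is carried forward). All other
#' features are imputed by k-nearest-neighbour: distances are standardized
#' Euclidean over the dimensions co-observed by each pair of blocks, and the
#' imputed value is the mean of the `k` nearest blocks observing that feature.
#' Anything still missing afterwards (for example a lab never measured before
#' a patient's first blocks) falls back to the training-population median.
#' Observed values are never altered.
#'
#' @param blocks Output of [segment_blocks()] (any number of patients).
#' @param labs Feature names to forward-fill (default [lab_features()]).
#' @param k Number of neighbours (default 5).
#' @param medians Optional named vector of per-feature fallback medians fitted
#'   on training data; when `NULL` they are computed from `blocks` and
#'   attached as attribute `medians` for reuse on held-out data.
#' @return The blocks with no missing state entries (attribute `medians`
#'   carries the fallback values used).
#' @export
impute_missing <- function(blocks, labs = lab_features(), k = 5L,
                           medians = NULL) {
  feats <- setdiff(state_features(), c("bloc"))
  missing_everywhere <- feats[vapply(feats, function(f) all(is.na(blocks[[f]])), TRUE)]
  if (length(missing_everywhere) && is.null(medians)) {
    stop("feature(s) missing for every block: ",
         paste(missing_everywhere, collapse = ", "), call. = FALSE)
  }
  blocks <- blocks[order(blocks$patient_id, blocks$bloc), , drop = FALSE]
  # 1. forward-fill labs within patient
  for (f in intersect(labs, names(blocks))) {
    v <- blocks[[f]]
    filled <- stats::ave(v, blocks$patient_id, FUN = function(x) {
      idx <- cumsum(!is.na(x))
      out <- x
      seen <- which(!is.na(x))
      if (length(seen)) out[idx > 0] <- x[seen][idx[idx > 0]]
      out
    })
    blocks[[f]] <- filled
  }
  # 2. KNN for the remaining features
  knn_feats <- setdiff(feats, labs)
  X <- as.matrix(blocks[, feats, drop = FALSE])
  mu <- colMeans(X, na.rm = TRUE)
  sg <- apply(X, 2, stats::sd, na.rm = TRUE)
  sg[!is.finite(sg) | sg == 0] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sg, "/")
  M <- !is.na(Xs)
  X0 <- Xs
  X0[!M] <- 0
  need <- which(rowSums(!M[, knn_feats, drop = FALSE]) > 0)
  if (length(need)) {
    chunk <- 512L
    for (start in seq(1, length(need), by = chunk)) {
      q <- need[start:min(start + chunk - 1L, length(need))]
      D <- co_observed_dist2(X0[q, , drop = FALSE], M[q, , drop = FALSE], X0, M)
      D[cbind(seq_along(q), q)] <- NA_real_  # never one's own block
      for (ii in seq_along(q)) {
        i <- q[ii]
        miss_f <- knn_feats[!M[i, knn_feats]]
        d <- D[ii, ]
        ord <- order(d, na.last = NA)
        for (f in miss_f) {
          cand <- ord[M[ord, f]]
          if (length(cand)) {
            nb <- cand[seq_len(min(k, length(cand)))]
            X[i, f] <- mean(X[nb, f])
          }
        }
      }
    }
  }
  # 3. median fallback for anything left
  if (is.null(medians)) {
    medians <- apply(as.matrix(blocks[, feats, drop = FALSE]), 2,
                     stats::median, na.rm = TRUE)
  }
  for (f in feats) {
    v <- X[, f]
    still <- is.na(v)
    if (any(still)) v[still] <- medians[[f]]
    blocks[[f]] <- v
  }
  rownames(blocks) <- NULL
  attr(blocks, "medians") <- medians
  blocks
}

#' Fit the quintile action bins
#'
#' The four cut points are the 20/40/60/80% quantiles of the *training-set*
#' fluid balances (linear interpolation between order statistics). Held-out
#' data must be discretized with bins fitted on training data only.
#'
#' @param balances Numeric vector of at least 5 finite training balances.
#' @return Object of class `action_bins` with field `edges` (4 ascending
#'   reals).
#' @examples
#' fit_action_bins(1:100)$edges  # 20.2 40.4 60.6 80.8
#' @export
fit_action_bins <- function(balances) {
  balances <- balances[is.finite(balances)]
  if (length(balances) < 5) {
    stop("need at least 5 finite balances to fit action bins", call. = FALSE)
  }
  edges <- unname(stats::quantile(balances, probs = c(0.2, 0.4, 0.6, 0.8),
                                  type = 6))
  structure(list(edges = edges), class = "action_bins")
}

#' Discretize fluid balance into the five actions
#'
#' Maps a continuous balance to action 0..4 with half-open intervals
#' `(-Inf, e1], (e1, e2], (e2, e3], (e3, e4], (e4, Inf)`: a value landing
#' exactly on an edge belongs to the lower bin. With degenerate (tied) edges
#' the value is assigned the middle of the tied bins, so an all-equal
#' training set maps everything to action 2.
#'
#' @param balance Numeric vector of finite balances.
#' @param bins An [fit_action_bins()] object.
#' @return Integer vector of actions 0..4.
#' @export
discretize_balance <- function(balance, bins) {
  if (!inherits(bins, "action_bins")) stop("bins must be action_bins", call. = FALSE)
  if (any(!is.finite(balance))) {
    stop("non-finite balance cannot be discretized", call. = FALSE)
  }
  e <- bins$edges
  lo <- vapply(balance, function(x) sum(e < x), 0L)
  hi <- vapply(balance, function(x) sum(e <= x), 0L)
  as.integer(floor((lo + hi) / 2))
}

#' Assign terminal survival rewards
#'
#' Each patient's last block gets reward +15 if they survived the ICU stay
#' and -15 if they died; every earlier block gets 0. The last block is
#' flagged terminal.
#'
#' @param blocks Block table with `patient_id` and `bloc`.
#' @param outcomes data.frame `patient_id`, `outcome` (1 = died).
#' @return `blocks` with `reward` and `terminal` columns.
#' @export
assign_rewards <- function(blocks, outcomes) {
  if (nrow(blocks) == 0) stop("empty block sequence", call. = FALSE)
  blocks <- blocks[order(blocks$patient_id, blocks$bloc), , drop = FALSE]
  last <- !duplicated(blocks$patient_id, fromLast = TRUE)
  died <- outcomes$outcome[match(blocks$patient_id, outcomes$patient_id)]
  if (any(is.na(died))) {
    stop("outcome missing for patient(s): ",
         paste(unique(blocks$patient_id[is.na(died)]), collapse = ", "),
         call. = FALSE)
  }
  blocks$reward <- ifelse(last, ifelse(died == 1, -15, 15), 0)
  blocks$terminal <- last
  rownames(blocks) <- NULL
  blocks
}

#' Random patient-level train/test split
#'
#' Patients (never individual blocks) are partitioned at random, so every
#' block of a patient falls on exactly one side.
#'
#' @param patient_ids Vector of unique patient identifiers (>= 2).
#' @param ratio Training fraction in (0, 1); default 0.8.
#' @param seed Integer seed making the partition reproducible.
#' @return List of class `split_dataset` with `train`, `test`, `ratio`,
#'   `seed`.
#' @export
split_patients <- function(patient_ids, ratio = 0.8, seed = 1L) {
  patient_ids <- unique(patient_ids)
  if (length(patient_ids) < 2) stop("need at least 2 patients to split", call. = FALSE)
  if (!is.numeric(ratio) || ratio <= 0 || ratio >= 1) {
    stop("ratio must lie strictly between 0 and 1", call. = FALSE)
  }
  set.seed(seed)
  n_train <- max(1L, min(length(patient_ids) - 1L,
                         as.integer(round(length(patient_ids) * ratio))))
  train <- sort(sample(patient_ids, n_train))
  structure(list(train = train,
                 test = sort(setdiff(patient_ids, train)),
                 ratio = ratio, seed = as.integer(seed)),
            class = "split_dataset")
}

#' Build SARSA/Q-learning transitions from rewarded blocks
#'
#' One transition per block: the next state and next action come from the
#' patient's next observed block; the final block of each stay is terminal
#' and carries no successor.
#'
#' @param blocks Imputed, discretized, rewarded blocks (must contain the 25
#'   state features plus `action`, `reward`, `terminal`).
#' @return Object of class `transition_set` with fields `states` (n x 25
#'   matrix), `actions`, `rewards`, `next_states`, `next_actions`,
#'   `terminal`, `patient_id`, `bloc`, `n_actions`.
#' @export
build_transitions <- function(blocks) {
  needed <- c(state_features(), "action", "reward", "terminal")
  miss <- setdiff(needed, names(blocks))
  if (length(miss)) {
    stop("blocks are missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  blocks <- blocks[order(blocks$patient_id, blocks$bloc), , drop = FALSE]
  S <- as.matrix(blocks[, state_features(), drop = FALSE])
  n <- nrow(S)
  same_next <- c(blocks$patient_id[-1] == blocks$patient_id[-n], FALSE)
  if (n == 1) same_next <- FALSE
  if (any(blocks$terminal & same_next) || any(!blocks$terminal & !same_next)) {
    stop("terminal flags inconsistent with patient block order", call. = FALSE)
  }
  next_idx <- ifelse(same_next, seq_len(n) + 1L, NA_integer_)
  structure(list(
    type = "network",
    states = S,
    actions = as.integer(blocks$action),
    rewards = as.numeric(blocks$reward),
    next_states = S[ifelse(is.na(next_idx), 1L, next_idx), , drop = FALSE],
    next_actions = ifelse(is.na(next_idx), NA_integer_,
                          as.integer(blocks$action[ifelse(is.na(next_idx), 1L, next_idx)])),
    terminal = as.logical(blocks$terminal),
    patient_id = blocks$patient_id,
    bloc = blocks$bloc,
    n_actions = 5L
  ), class = "transition_set")
}

#' Tabular transition set for enumerable toy problems
#'
#' States are integer identifiers 1..`n_states`; used by the tabular learners
#' and the dynamic-programming oracle tests.
#'
#' @param states,actions,rewards,next_states,next_actions,terminal Aligned
#'   vectors; `next_*` entries at terminal rows are ignored.
#' @param n_states,n_actions Table dimensions.
#' @return A `transition_set` with `type = "tabular"`.
#' @export
tabular_transitions <- function(states, actions, rewards, next_states,
                                next_actions, terminal, n_states,
                                n_actions = 5L) {
  stopifnot(length(actions) == length(states),
            length(rewards) == length(states),
            length(terminal) == length(states))
  structure(list(
    type = "tabular",
    states = as.integer(states),
    actions = as.integer(actions),
    rewards = as.numeric(rewards),
    next_states = as.integer(next_states),
    next_actions = suppressWarnings(as.integer(next_actions)),
    terminal = as.logical(terminal),
    n_states = as.integer(n_states),
    n_actions = as.integer(n_actions)
  ), class = "transition_set")
}

#' Compare feature distributions across a patient split
#'
#' For each state feature, reports medians with interquartile ranges on both
#' sides of the split and the Wilcoxon rank-sum p-value, flagging features
#' whose distributions differ at the 0.01 level.
#'
#' @param train_blocks,test_blocks Block tables with the state feature
#'   columns.
#' @param alpha Flagging level (default 0.01).
#' @return data.frame with one row per feature.
#' @export
check_split_balance <- function(train_blocks, test_blocks, alpha = 0.01) {
  if (nrow(train_blocks) == 0 || nrow(test_blocks) == 0) {
    stop("both sides of the split must be non-empty", call. = FALSE)
  }
  feats <- intersect(c(state_features(), "balance"), names(train_blocks))
  res <- lapply(feats, function(f) {
    x <- train_blocks[[f]]
    y <- test_blocks[[f]]
    p <- tryCatch(
      suppressWarnings(stats::wilcox.test(x, y, exact = FALSE)$p.value),
      error = function(e) NA_real_)
    if (is.na(p)) p <- 1  # identical constant samples
    qs_x <- stats::quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE)
    qs_y <- stats::quantile(y, c(0.25, 0.5, 0.75), na.rm = TRUE)
    data.frame(feature = f,
               train_median = qs_x[2], train_q25 = qs_x[1], train_q75 = qs_x[3],
               test_median = qs_y[2], test_q25 = qs_y[1], test_q75 = qs_y[3],
               p_value = p, flagged = p < alpha)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# Basic records-table validation shared by the readers and preprocessing.
validate_records <- function(records) {
  required <- c("patient_id", "block_time_hours", "feature", "value")
  miss <- setdiff(required, names(records))
  if (length(miss)) {
    stop("records table is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (nrow(records) > 0) {
    if (!is.numeric(records$block_time_hours)) {
      stop("column block_time_hours must be numeric", call. = FALSE)
    }
    if (any(records$block_time_hours < 0, na.rm = TRUE)) {
      stop("block_time_hours must be >= 0", call. = FALSE)
    }
    if (!is.numeric(records$value)) {
      stop("column value must be numeric", call. = FALSE)
    }
  }
  invisible(records)
}
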