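# Descriptive analyses relating learned Q-values and predicted fluid
# strategies to observed ICU mortality. Mortality is computed over blocks:
# every block inherits its patient's terminal outcome (a per-patient variant,
# keeping only terminal blocks, is available via `per_patient = TRUE`).

# Equal-frequency bin assignment: bin sizes differ by at most one; ties are
# resolved by original order, deterministically.
equal_freq_bins <- function(x, n_bins) {
  n <- length(x)
  if (n_bins < 2) stop("n_bins must be >= 2", call. = FALSE)
  if (n_bins > n) stop("more bins than observations", call. = FALSE)
  ord <- order(x)
  sizes <- rep(n %/% n_bins, n_bins)
  extra <- n %% n_bins
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  bins <- integer(n)
  bins[ord] <- rep(seq_len(n_bins), times = sizes)
  bins
}

mortality_curve <- function(x, died, n_bins, x_name) {
  bins <- equal_freq_bins(x, n_bins)
  rows <- lapply(seq_len(n_bins), function(b) {
    i <- bins == b
    data.frame(bin = b, n = sum(i), deaths = sum(died[i]),
               mortality = mean(died[i]),
               x_lo = min(x[i]), x_hi = max(x[i]), x_mid = mean(x[i]))
  })
  out <- do.call(rbind, rows)
  attr(out, "x_name") <- x_name
  class(out) <- c("mortality_curve", class(out))
  out
}

#' Mortality versus expected reward
#'
#' Computes each block's expected reward `Q(s, a_logged)` under a trained
#' (typically SARSA) model, bins blocks into equal-frequency bins of expected
#' reward, and reports per-bin mortality. On well-calibrated data mortality
#' falls as the expected reward rises.
#'
#' @param q Trained Q-function, or a precomputed numeric vector of per-block
#'   expected rewards.
#' @param blocks Blocks with state features, `action` and `patient_id`.
#' @param outcomes data.frame `patient_id`, `outcome` (1 = died).
#' @param n_bins Number of equal-frequency bins (>= 2, default 10).
#' @param per_patient Use only terminal blocks (default `FALSE` = all
#'   blocks).
#' @return A `mortality_curve` data.frame (bin, n, deaths, mortality, bin
#'   value range).
#' @export
mortality_by_expected_reward <- function(q, blocks, outcomes, n_bins = 10L,
                                         per_patient = FALSE) {
  if (per_patient) blocks <- blocks[blocks$terminal, , drop = FALSE]
  died <- outcomes$outcome[match(blocks$patient_id, outcomes$patient_id)]
  er <- if (is.numeric(q) && is.null(dim(q))) {
    if (length(q) != nrow(blocks)) {
      stop("expected-reward vector length mismatch", call. = FALSE)
    }
    q
  } else {
    qv <- q_values(q, as.matrix(blocks[, state_features(), drop = FALSE]))
    qv[cbind(seq_len(nrow(qv)), blocks$action + 1L)]
  }
  mortality_curve(er, died, n_bins, "expected_reward")
}

#' Action distribution
#'
#' Five-bin histogram of fluid-balance actions; the clinical and AI
#' distributions share this code path.
#'
#' @param actions Integer vector of actions 0..4.
#' @return data.frame `action`, `count`, `proportion`.
#' @export
action_distribution <- function(actions) {
  if (any(is.na(actions)) || any(!actions %in% 0:4)) {
    stop("actions must lie in 0..4", call. = FALSE)
  }
  counts <- tabulate(actions + 1L, nbins = 5L)
  data.frame(action = 0:4, count = counts,
             proportion = counts / length(actions))
}

#' Representative balance per action bin
#'
#' The per-bin medians of the training balances falling in each action bin
#' (medians rather than interval midpoints: the outer bins are open-ended).
#' Used as the predicted continuous balance of a predicted action.
#'
#' @param balances Training-set balances.
#' @param bins An [fit_action_bins()] object.
#' @return Numeric vector of 5 representative balances, ascending.
#' @export
bin_median_balance <- function(balances, bins) {
  a <- discretize_balance(balances, bins)
  sapply(0:4, function(k) {
    v <- balances[a == k]
    if (!length(v)) stop("action bin ", k, " holds no training balances",
                         call. = FALSE)
    stats::median(v)
  })
}

#' Mortality versus predicted-minus-real balance difference
#'
#' Maps each predicted action to its representative balance, subtracts the
#' actually logged balance, bins the differences (equal frequency) and
#' reports per-bin mortality. When deviation from the optimal strategy is
#' harmful, mortality is lowest near zero difference and rises toward both
#' tails; both tails are reported without assuming which is worse.
#'
#' @param predicted_actions Integer vector of predicted actions 0..4.
#' @param balances Logged continuous balances, aligned.
#' @param died 0/1 outcome per block (each block inherits its patient's
#'   terminal outcome).
#' @param representatives Output of [bin_median_balance()].
#' @param n_bins Number of equal-frequency bins (default 10).
#' @return A `mortality_curve` over the balance difference.
#' @export
balance_difference_mortality <- function(predicted_actions, balances, died,
                                         representatives, n_bins = 10L) {
  if (any(!predicted_actions %in% 0:4)) {
    stop("actions must lie in 0..4", call. = FALSE)
  }
  diffs <- representatives[predicted_actions + 1L] - balances
  mortality_curve(diffs, died, n_bins, "balance_difference")
}

#' Binarize the five actions into balance direction
#'
#' Actions 0, 1 and 2 become class 0 (negative fluid balance, net removal);
#' actions 3 and 4 become class 1 (positive balance, net infusion).
#'
#' @param actions Integer vector of actions 0..4.
#' @return Integer vector of 0/1 balance classes.
#' @export
binarize_actions <- function(actions) {
  if (any(is.na(actions)) || any(!actions %in% 0:4)) {
    stop("actions must lie in 0..4", call. = FALSE)
  }
  as.integer(actions >= 3)
}

#' Concordance mortality of predicted versus actual balance direction
#'
#' Cross-tabulates the binarized predicted and actual balance directions into
#' four cells, reports per-cell survivor/death block counts and mortality,
#' and a chi-square test of mortality differences across the cells.
#'
#' @param predicted_binary,actual_binary 0/1 balance classes per block.
#' @param died 0/1 outcome per block.
#' @return Object of class `concordance_table`: data.frame with one row per
#'   cell (`predicted`, `actual`, `survivors`, `deaths`, `n`, `mortality`)
#'   and attributes `chisq_p` and `chisq_statistic`.
#' @export
concordance_mortality <- function(predicted_binary, actual_binary, died) {
  n <- length(predicted_binary)
  if (n == 0) stop("empty input", call. = FALSE)
  if (length(actual_binary) != n || length(died) != n) {
    stop("inputs must be aligned", call. = FALSE)
  }
  if (any(!predicted_binary %in% 0:1) || any(!actual_binary %in% 0:1)) {
    stop("binary classes must be 0/1", call. = FALSE)
  }
  grid <- expand.grid(predicted = 0:1, actual = 0:1)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    idx <- predicted_binary == grid$predicted[i] &
      actual_binary == grid$actual[i]
    data.frame(predicted = grid$predicted[i], actual = grid$actual[i],
               survivors = sum(idx & died == 0), deaths = sum(idx & died == 1),
               n = sum(idx),
               mortality = if (any(idx)) mean(died[idx]) else NA_real_)
  })
  out <- do.call(rbind, rows)
  tab <- cbind(out$deaths, out$survivors)
  keep <- out$n > 0
  p <- tryCatch(
    suppressWarnings(stats::chisq.test(tab[keep, , drop = FALSE])),
    error = function(e) list(p.value = NA_real_, statistic = NA_real_))
  attr(out, "chisq_p") <- p$p.value
  attr(out, "chisq_statistic") <- unname(p$statistic)
  class(out) <- c("concordance_table", class(out))
  out
}

#' @export
print.concordance_table <- function(x, ...) {
  cat("Concordance of predicted vs actual balance direction",
      sprintf("(chi-square p = %.3g)\n", attr(x, "chisq_p")))
  print.data.frame(x, ...)
  invisible(x)
}

#' Plot a mortality curve
#'
#' @param x A `mortality_curve`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot.mortality_curve <- function(x, ...) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  ggplot2::ggplot(x, ggplot2::aes(x = x_mid, y = mortality)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = attr(x, "x_name"), y = "mortality") +
    ggplot2::theme_minimal()
}

#' Plot a clinical vs AI action distribution comparison
#'
#' @param clinical,ai Outputs of [action_distribution()].
#' @return A ggplot object.
#' @export
plot_action_distributions <- function(clinical, ai) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  clinical$policy <- "clinical"
  ai$policy <- "AI"
  d <- rbind(clinical, ai)
  ggplot2::ggplot(d, ggplot2::aes(x = factor(action),
                                  y = proportion,
                                  fill = policy)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "action", y = "proportion") +
    ggplot2::theme_minimal()
}
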