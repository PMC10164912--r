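#' Matrix assessment score (MAS)
#'
#' The training objective: how well a scoring matrix separates the positive
#' score distribution from the negative one. With P, N the medians and
#' Pstd, Nstd the sample standard deviations of the positive and negative
#' scores, the default (`variant = "gap"`) objective is
#'
#' \deqn{MAS = (P - Pstd - N - Nstd) / P}
#'
#' i.e. the gap between the lower edge of the positive distribution and the
#' upper edge of the negative one, normalized by the positive median. A
#' second reading of the formula, `variant = "literal"`, uses
#' `(P - Pstd - N + Nstd) / P`; it rewards a wider negative spread and is
#' provided for comparison only (see the methods vignette).
#'
#' Medians of even-length score lists are the mean of the middle two;
#' singleton lists have standard deviation 0. The objective is undefined
#' when P = 0, which is an error here.
#'
#' @param positive_scores,negative_scores Non-empty numeric vectors.
#' @param variant `"gap"` (default) or `"literal"`.
#' @return An object of class `mas_report`: list with elements `P`, `N`,
#'   `Pstd`, `Nstd`, `mas`, `variant`.
#' @examples
#' mas(c(100, 120, 140), c(40, 50, 60))$mas  # 1/3
#' @export
mas <- function(positive_scores, negative_scores,
                variant = c("gap", "literal")) {
  variant <- match.arg(variant)
  if (length(positive_scores) == 0L || length(negative_scores) == 0L) {
    stop("both score vectors must be non-empty")
  }
  stopifnot(is.numeric(positive_scores), is.numeric(negative_scores))
  P <- stats::median(positive_scores)
  N <- stats::median(negative_scores)
  Pstd <- if (length(positive_scores) > 1L) stats::sd(positive_scores) else 0
  Nstd <- if (length(negative_scores) > 1L) stats::sd(negative_scores) else 0
  if (P == 0) {
    stop("MAS is undefined when the positive median P is 0")
  }
  m <- mas_value(P, N, Pstd, Nstd, variant)
  structure(list(P = P, N = N, Pstd = Pstd, Nstd = Nstd, mas = m,
                 variant = variant),
            class = "mas_report")
}

mas_value <- function(P, N, Pstd, Nstd, variant) {
  if (variant == "literal") {
    (P - Pstd - N + Nstd) / P
  } else {
    (P - Pstd - N - Nstd) / P
  }
}

#' @export
print.mas_report <- function(x, ...) {
  cat("<mas_report> MAS = ", format(x$mas), " (", x$variant, ")\n",
      "  P = ", format(x$P), " (sd ", format(x$Pstd), "), N = ",
      format(x$N), " (sd ", format(x$Nstd), ")\n", sep = "")
  invisible(x)
}

#' Optimizer configuration
#'
#' Settings for the stochastic hill climber in [optimize_matrix()]. One
#' seeded generator drives matrix initialization, cell choice and
#' perturbation sign, so a config plus identical datasets reproduces the
#' trained matrix bit for bit.
#'
#' @param seed Integer random seed (mandatory).
#' @param iterations Number of proposal steps (default 100000).
#' @param step_size Magnitude of a single-cell perturbation (default 1).
#' @param init `"uniform"` (default) draws every initial cell from
#'   `runif(0, init_range)` — arbitrary positive starting scores, which keep
#'   the positive-set median positive as the normalized objective requires.
#'   `"zero"` starts from the all-zero matrix; note that this start is
#'   degenerate under strict-improvement hill climbing (a single-cell
#'   perturbation cannot move either score median off zero, so MAS remains
#'   undefined and no move is ever accepted) and is provided only as an
#'   explicit null.
#' @param init_range Upper bound of the uniform initialization (default 1).
#' @param variant MAS variant passed through to the objective.
#' @param report_every Record the trajectory every this many iterations in
#'   addition to every accepted step (default 1 = every iteration).
#' @return An object of class `optimizer_config`.
#' @export
optimizer_config <- function(seed, iterations = 100000L, step_size = 1,
                             init = c("uniform", "zero"), init_range = 1,
                             variant = c("gap", "literal"),
                             report_every = 1L) {
  init <- match.arg(init)
  variant <- match.arg(variant)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  iterations <- as.integer(iterations)
  stopifnot(iterations >= 0L)
  stopifnot(is.numeric(step_size), step_size > 0)
  stopifnot(is.numeric(init_range), init_range > 0)
  report_every <- as.integer(report_every)
  stopifnot(report_every >= 1L)
  structure(
    list(seed = as.integer(seed), iterations = iterations,
         step_size = step_size, init = init, init_range = init_range,
         variant = variant, report_every = report_every),
    class = "optimizer_config"
  )
}

#' Train a scoring matrix by randomized hill climbing
#'
#' Starting from a uniform-random (or all-zero) matrix, each iteration
#' perturbs one uniformly chosen cell by +/- `step_size` (equal
#' probability) and keeps the change iff the MAS strictly increases.
#' Because only improving moves are kept, the accepted-step MAS trace is
#' strictly increasing and the final matrix attains the maximum MAS seen.
#' Scores are updated incrementally (a single-cell change only shifts the
#' scores of windows carrying that residue at that offset), so runs with
#' tens of thousands of iterations take seconds.
#'
#' The P-normalized objective is meaningful only while the positive-set
#' median is positive: proposals that would drive it to zero or below are
#' treated as objective minus-infinity and rejected, and states with an
#' undefined objective are recorded as `NA` in the trajectory.
#'
#' @param positive,negative `peptide_set` objects of equal window length
#'   with the corresponding labels.
#' @param config An [optimizer_config()].
#' @return A list of class `matrix_optimization` with elements `matrix`
#'   (the trained [scoring_matrix()]), `initial_matrix` (the starting
#'   matrix, so that `matrix - initial_matrix` isolates what was learned),
#'   `trajectory` (data frame `iteration`, `mas`, `accepted`, including
#'   iteration 0 = the initial state), `initial_mas`, `final_mas`,
#'   `accepted` (number of accepted moves) and `config`.
#' @export
optimize_matrix <- function(positive, negative, config) {
  stopifnot(inherits(positive, "peptide_set"),
            inherits(negative, "peptide_set"),
            inherits(config, "optimizer_config"))
  if (positive$label != "positive" || negative$label != "negative") {
    stop("arguments must be a positive- and a negative-labeled set, ",
         "in that order")
  }
  if (positive$window_length != negative$window_length) {
    stop("window lengths differ: positive ", positive$window_length,
         ", negative ", negative$window_length)
  }
  if (set_size(positive) == 0L || set_size(negative) == 0L) {
    stop("both peptide sets must be non-empty")
  }
  L <- positive$window_length
  n_aa <- length(AA_MATRIX)
  n_off <- L - 1L

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(config$seed)

  init_vals <- if (config$init == "uniform") {
    matrix(stats::runif(n_aa * n_off, 0, config$init_range), n_aa, n_off)
  } else {
    matrix(0, n_aa, n_off)
  }
  m <- scoring_matrix(L, values = init_vals, name = "trained")
  m0 <- scoring_matrix(L, values = init_vals, name = "initial")

  # integer-encode windows once: row = window, col = offset, value = matrix
  # row index of the residue (NA for W/C/X/pad)
  enc <- function(set) {
    chars <- matrix(unlist(strsplit(set$windows$window, "", fixed = TRUE),
                           use.names = FALSE),
                    nrow = set_size(set), ncol = L, byrow = TRUE)
    flank <- (L - 1L) %/% 2L
    cols <- setdiff(seq_len(L), flank + 1L)
    matrix(match(chars[, cols], AA_MATRIX), nrow = nrow(chars))
  }
  pos_enc <- enc(positive)
  neg_enc <- enc(negative)

  score_enc <- function(encoded) {
    s <- numeric(nrow(encoded))
    for (j in seq_len(n_off)) {
      idx <- encoded[, j]
      hit <- !is.na(idx)
      s[hit] <- s[hit] + m[idx[hit], j]
    }
    s
  }
  pos_scores <- score_enc(pos_enc)
  neg_scores <- score_enc(neg_enc)

  objective <- function(ps, ns) {
    P <- stats::median(ps)
    if (P <= 0) return(NA_real_)
    mas_value(P, stats::median(ns), stats::sd(ps), stats::sd(ns),
              config$variant)
  }
  cur <- objective(pos_scores, neg_scores)
  cur_cmp <- if (is.na(cur)) -Inf else cur
  initial_mas <- cur

  iters <- config$iterations
  traj_iter <- integer(iters + 1L)
  traj_mas <- numeric(iters + 1L)
  traj_acc <- logical(iters + 1L)
  traj_iter[1L] <- 0L
  traj_mas[1L] <- cur
  traj_acc[1L] <- FALSE
  n_rec <- 1L
  n_accepted <- 0L

  for (i in seq_len(iters)) {
    cell_aa <- sample.int(n_aa, 1L)
    cell_off <- sample.int(n_off, 1L)
    delta <- if (stats::runif(1) < 0.5) config$step_size else -config$step_size
    hit_p <- which(pos_enc[, cell_off] == cell_aa)
    hit_n <- which(neg_enc[, cell_off] == cell_aa)
    ps <- pos_scores
    ns <- neg_scores
    if (length(hit_p)) ps[hit_p] <- ps[hit_p] + delta
    if (length(hit_n)) ns[hit_n] <- ns[hit_n] + delta
    cand <- objective(ps, ns)
    accept <- !is.na(cand) && cand > cur_cmp
    if (accept) {
      m[cell_aa, cell_off] <- m[cell_aa, cell_off] + delta
      pos_scores <- ps
      neg_scores <- ns
      cur <- cand
      cur_cmp <- cand
      n_accepted <- n_accepted + 1L
    }
    if (accept || i %% config$report_every == 0L || i == iters) {
      n_rec <- n_rec + 1L
      traj_iter[n_rec] <- i
      traj_mas[n_rec] <- if (accept) cand else cur
      traj_acc[n_rec] <- accept
    }
  }

  trajectory <- data.frame(
    iteration = traj_iter[seq_len(n_rec)],
    mas = traj_mas[seq_len(n_rec)],
    accepted = traj_acc[seq_len(n_rec)]
  )
  structure(
    list(matrix = m, initial_matrix = m0, trajectory = trajectory,
         initial_mas = initial_mas, final_mas = cur,
         accepted = n_accepted, config = config),
    class = "matrix_optimization"
  )
}

#' @export
print.matrix_optimization <- function(x, ...) {
  cat("<matrix_optimization> ", x$config$iterations, " iterations, ",
      x$accepted, " accepted\n", sep = "")
  cat("  MAS: ",
      if (is.na(x$initial_mas)) "undefined (zero init)"
      else format(x$initial_mas),
      " -> ", format(x$final_mas), "\n", sep = "")
  invisible(x)
}

#' Write an optimization trajectory to TSV
#'
#' @param fit A `matrix_optimization` result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_tsv <- function(fit, path) {
  stopifnot(inherits(fit, "matrix_optimization"))
  utils::write.table(fit$trajectory, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
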