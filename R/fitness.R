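## Euler-Lotka fitness estimation from brood records and treatment-effect
## summaries with bootstrap intervals.

#' Intrinsic rate of population increase from two broods
#'
#' Solves the Euler equation
#' `brood1 * exp(-r * age1) + brood2 * exp(-r * age2) = 1`
#' for `r` (per day) by bracketed root finding; survivorship to each brood is
#' taken as 1 (clonal laboratory conditions, only individuals surviving to
#' record broods enter the table). The left side is strictly decreasing in
#' `r`, so the root is unique. The search bracket `[-5, 5]` is widened
#' automatically if the sign change lies outside.
#'
#' @param age1,age2 Ages at first and second brood, days.
#' @param brood1,brood2 Brood sizes (offspring counts).
#' @param interval Initial search bracket for `r` (per day).
#' @param tol Root tolerance.
#' @return `r` per day, or `NA` when both broods are zero (undefined
#'   fitness).
#' @export
euler_r <- function(age1, brood1, age2 = NA, brood2 = 0,
                    interval = c(-5, 5), tol = 1e-8) {
  if (is.na(brood2) || (is.na(age2) && brood2 == 0)) brood2 <- 0
  if (brood1 == 0 && brood2 == 0) return(NA_real_)
  if (age1 <= 0 || (brood2 > 0 && (is.na(age2) || age2 <= age1)))
    stop("ages must be positive with age2 > age1")
  f <- function(r) brood1 * exp(-r * age1) +
    (if (brood2 > 0) brood2 * exp(-r * age2) else 0) - 1
  lo <- interval[1]; hi <- interval[2]
  while (f(lo) < 0) lo <- lo * 2
  while (f(hi) > 0) hi <- hi * 2
  stats::uniroot(f, c(lo, hi), tol = tol)$root
}

#' Per-individual fitness for a life-history table
#'
#' @param table data.frame of life-history records (see
#'   [simulate_lifehistory()] for the column layout).
#' @return The table with an `r` column appended (`NA` for individuals with
#'   no offspring, which are excluded from group means downstream).
#' @export
individual_fitness <- function(table) {
  table$r <- vapply(seq_len(nrow(table)), function(i)
    euler_r(table$age_first_repro[i], table$brood1_size[i],
            table$age_second_repro[i], table$brood2_size[i]), 0)
  table
}

.clone_center <- function(tab) {
  mu <- mean(tab$r)
  cl_mu <- tapply(tab$r, tab$clone_line, mean)
  tab$r_centered <- tab$r - cl_mu[tab$clone_line] + mu
  tab
}

.cell_effects <- function(tab) {
  cells <- unique(tab[tab$treatment != "control",
                      c("experiment", "treatment", "generation")])
  cells <- cells[order(cells$experiment, cells$treatment, cells$generation), ]
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    cc <- cells[i, ]
    tr <- tab$r_centered[tab$experiment == cc$experiment &
                           tab$treatment == cc$treatment &
                           tab$generation == cc$generation]
    ct <- tab$r_centered[tab$experiment == cc$experiment &
                           tab$treatment == "control" &
                           tab$generation == cc$generation]
    data.frame(cc, n_case = length(tr), n_control = length(ct),
               effect = if (length(tr) && length(ct)) mean(tr) - mean(ct)
                        else NA_real_)
  })
  do.call(rbind, rows)
}

#' Treatment-by-generation fitness effects with bootstrap intervals
#'
#' Removes clone-line effects by centering `r` within clone line, then
#' estimates each treatment x generation effect as the difference in mean
#' centered fitness against the matched control cell (same generation, same
#' experiment). 95% intervals come from a stratified nonparametric bootstrap
#' resampling individuals within treatment x generation x experiment cells.
#' Individuals with undefined fitness (no offspring) are excluded and
#' counted.
#'
#' @param table Life-history data.frame (with or without an `r` column).
#' @param n_boot Bootstrap replicates.
#' @param seed Integer seed for the bootstrap stream.
#' @param conf Interval coverage level.
#' @return A `fitness_estimate` list: `individuals` (table with r and
#'   clone-centered r), `effects` (per-cell effect, lower, upper),
#'   `n_undefined`.
#' @export
fitness_effects <- function(table, n_boot = 4000, seed = 1, conf = 0.95) {
  if (is.null(table$r)) table <- individual_fitness(table)
  n_undef <- sum(is.na(table$r))
  tab <- table[!is.na(table$r), , drop = FALSE]
  cell_id <- interaction(tab$experiment, tab$treatment, tab$generation,
                         drop = TRUE)
  small <- table(cell_id)
  if (any(small < 2)) stop("each treatment x generation cell needs >= 2 ",
                           "individuals with defined fitness")
  tab <- .clone_center(tab)
  obs <- .cell_effects(tab)
  set.seed(seed)
  strata <- split(seq_len(nrow(tab)), cell_id)
  boot <- matrix(NA_real_, n_boot, nrow(obs))
  for (b in seq_len(n_boot)) {
    idx <- unlist(lapply(strata, function(s) s[sample.int(length(s),
                                                          replace = TRUE)]),
                  use.names = FALSE)
    bt <- .clone_center(tab[idx, , drop = FALSE])
    boot[b, ] <- .cell_effects(bt)$effect
  }
  alpha <- (1 - conf) / 2
  obs$lower <- apply(boot, 2, stats::quantile, probs = alpha, na.rm = TRUE)
  obs$upper <- apply(boot, 2, stats::quantile, probs = 1 - alpha, na.rm = TRUE)
  rownames(obs) <- NULL
  structure(list(individuals = tab, effects = obs, n_undefined = n_undef),
            class = "fitness_estimate")
}

#' @export
print.fitness_estimate <- function(x, ...) {
  cat("fitness_estimate:", nrow(x$effects), "treatment x generation cells,",
      x$n_undefined, "individual(s) with undefined fitness\n")
  print(x$effects, digits = 3)
  invisible(x)
}
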