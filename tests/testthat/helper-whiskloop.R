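# shared builders for the test suite; everything is generated in code

# construct a whisk_psth directly from analytic bin rates
make_psth <- function(rates, window = c(-200, 100), bin_width = 2,
                      n_sweeps = 30, alignment = "deflection") {
  nbins <- as.integer(diff(window) / bin_width)
  stopifnot(length(rates) == nbins)
  structure(list(
    bin_edges = window[1] + bin_width * (0:nbins),
    rate = rates,
    counts = rates * n_sweeps * bin_width / 1000,
    n_sweeps = n_sweeps,
    bin_width = bin_width,
    window = window,
    alignment = alignment,
    state_label = NA_character_
  ), class = "whisk_psth")
}

# flat PSTH at a constant rate
flat_psth <- function(rate, window = c(-200, 100), bin_width = 2,
                      n_sweeps = 30) {
  nbins <- as.integer(diff(window) / bin_width)
  make_psth(rep(rate, nbins), window, bin_width, n_sweeps)
}

# quick all-quiet state configuration (no whisking episodes)
quiet_states <- function(...) state_config(whisk_mean_ms = 0, ...)

# a small session for pipeline-level tests
small_population <- function() {
  default_unit_population(n_tagged = 3, n_l6_other = 2, n_other_layers = 2,
                          n_interneurons = 1, n_pom = 3, n_vpm = 2)
}

# independent brute-force sums-of-squares oracle for a balanced 2x2
# within-subject table (columns subject,row,col,value); returns the SS
# decomposition computed purely from marginal means
brute_force_rm_ss <- function(df) {
  v <- stats::xtabs(value ~ subject + row + col, data = df)
  n <- dim(v)[1]
  gm <- mean(v)
  subj_means <- apply(v, 1, mean)
  row_means <- apply(v, 2, mean)
  col_means <- apply(v, 3, mean)
  cell_means <- apply(v, c(2, 3), mean)
  ss_total <- sum((v - gm)^2)
  ss_subj <- prod(dim(v)[2:3]) * sum((subj_means - gm)^2)
  ss_row <- n * dim(v)[3] * sum((row_means - gm)^2)
  ss_col <- n * dim(v)[2] * sum((col_means - gm)^2)
  ss_cells <- n * sum((cell_means - gm)^2)
  ss_rowcol <- ss_cells - ss_row - ss_col
  rs_means <- apply(v, c(1, 2), mean)
  ss_rowsubj <- dim(v)[3] *
    sum((sweep(sweep(rs_means, 1, subj_means), 2, row_means) + gm)^2)
  cs_means <- apply(v, c(1, 3), mean)
  ss_colsubj <- dim(v)[2] *
    sum((sweep(sweep(cs_means, 1, subj_means), 2, col_means) + gm)^2)
  ss_err <- ss_total - ss_subj - ss_row - ss_col - ss_rowcol -
    ss_rowsubj - ss_colsubj
  list(total = ss_total, subject = ss_subj,
       row = ss_row, col = ss_col, interaction = ss_rowcol,
       row_err = ss_rowsubj, col_err = ss_colsubj, interaction_err = ss_err,
       F_row = (ss_row / (dim(v)[2] - 1)) / (ss_rowsubj / ((dim(v)[2] - 1) * (n - 1))),
       F_col = (ss_col / (dim(v)[3] - 1)) / (ss_colsubj / ((dim(v)[3] - 1) * (n - 1))),
       F_int = (ss_rowcol / ((dim(v)[2] - 1) * (dim(v)[3] - 1))) /
         (ss_err / ((dim(v)[2] - 1) * (dim(v)[3] - 1) * (n - 1))))
}
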