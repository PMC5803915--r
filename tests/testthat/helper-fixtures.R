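# Small in-code fixtures: toy region tables and connectomes used across tests.

make_region_table <- function(ns = 6, nf = 4, volume = 10) {
  stopifnot(nf <= ns)
  func <- rep(NA_integer_, ns)
  func[seq_len(nf)] <- seq_len(nf)
  validate_region_table(tibble::tibble(
    region_name = paste("Region", seq_len(ns)),
    hemisphere = rep(c("right", "left"), length.out = ns),
    structural_index = seq_len(ns),
    functional_index = func,
    tissue_class = ifelse(is.na(func), "WM", "GM"),
    volume_mm3 = rep_len(volume, ns)
  ))
}

connectome_from_matrix <- function(w, kind = "binary", volume = 10) {
  n <- nrow(w)
  tab <- make_region_table(ns = n, nf = n, volume = volume)
  new_connectome(w, structural_nodes(tab), kind)
}

path_graph <- function(n) {
  w <- matrix(0, n, n)
  for (i in seq_len(n - 1)) w[i, i + 1] <- w[i + 1, i] <- 1
  w
}

complete_graph <- function(n) {
  w <- matrix(1, n, n)
  diag(w) <- 0
  w
}

small_cohort_config <- function(seed = 1, n_per_group = 4, ns = 16, nf = 10,
                                n_timepoints = 200, ...) {
  cohort_config(seed = seed, n_per_group = n_per_group,
                region_table = make_region_table(ns = ns, nf = nf),
                n_timepoints = n_timepoints, ...)
}
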