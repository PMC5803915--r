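#' Read and validate a brain region table
#'
#' The region table is the parcellation catalogue that defines network nodes:
#' one row per hemisphere-region with its 1-based index in the structural
#' connectome, its index in the functional connectome (absent for regions made
#' up only of white matter, which carry no BOLD signal of interest), a tissue
#' class and a region volume in cubic millimetres. Volumes enter the fiber
#' density edge weight, which normalises streamline counts by the product of
#' the two endpoint region volumes.
#'
#' Validation enforces the structural invariants the rest of the pipeline
#' relies on: structural indexes are unique and form a contiguous `1..Ns`
#' range, functional indexes a contiguous `1..Nf` range, every functional node
#' is also a structural node, white-matter regions carry no functional index,
#' and volumes are strictly positive.
#'
#' @param path Path to a TSV/CSV file with columns `region_name`,
#'   `hemisphere` (`right`, `left` or `midline`), `structural_index`,
#'   `functional_index` (empty cell = absent), `tissue_class`
#'   (`GM`, `WM` or `mixed`) and `volume_mm3`.
#' @return A validated tibble (class `region_table`).
#' @examples
#' tab <- read_region_table(example_region_table_path())
#' nrow(tab)                      # 76 hemisphere-regions
#' sum(!is.na(tab$functional_index))  # 54 functional nodes
#' @export
read_region_table <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("region table file not found: ", path))
  }
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- readr::read_delim(
    path, delim = delim, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      region_name = readr::col_character(),
      hemisphere = readr::col_character(),
      structural_index = readr::col_integer(),
      functional_index = readr::col_integer(),
      tissue_class = readr::col_character(),
      volume_mm3 = readr::col_double()
    )
  )
  validate_region_table(tab)
}

#' Path to the packaged example region table
#'
#' A 76-region rat-brain parcellation (38 regions per hemisphere) with 54
#' gray-matter regions indexed as functional nodes. Region names and node
#' indexes follow the combined rat atlas parcellation used for rodent
#' connectome studies; the region volumes in this file are synthetic
#' placeholders (the source atlas publishes no volumes) and real analyses
#' must supply their own.
#'
#' @return Path to the TSV file shipped with the package.
#' @export
example_region_table_path <- function() {
  system.file("extdata", "region_table_synthetic_volumes.tsv",
              package = "ratconnectome", mustWork = TRUE)
}

#' Validate a region table
#'
#' @param tab A data frame with the region-table columns (see
#'   [read_region_table()]).
#' @return The table as a validated `region_table` tibble.
#' @export
validate_region_table <- function(tab) {
  required <- c("region_name", "hemisphere", "structural_index",
                "functional_index", "tissue_class", "volume_mm3")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0) {
    abort(paste0("region table is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  tab <- as_tibble(tab)
  bad_hemi <- !tab$hemisphere %in% c("right", "left", "midline")
  if (any(bad_hemi)) {
    abort(paste0("invalid hemisphere in row(s) ",
                 paste(which(bad_hemi), collapse = ", ")))
  }
  bad_tissue <- !tab$tissue_class %in% c("GM", "WM", "mixed")
  if (any(bad_tissue)) {
    abort(paste0("invalid tissue_class in row(s) ",
                 paste(which(bad_tissue), collapse = ", ")))
  }
  bad_vol <- !is.finite(tab$volume_mm3) | tab$volume_mm3 <= 0
  if (any(bad_vol)) {
    abort(paste0("non-positive volume in row(s) ",
                 paste(which(bad_vol), collapse = ", ")))
  }
  check_contiguous_index(tab$structural_index, "structural_index")
  check_contiguous_index(tab$functional_index, "functional_index")
  func_no_struct <- !is.na(tab$functional_index) & is.na(tab$structural_index)
  if (any(func_no_struct)) {
    abort(paste0("row(s) with a functional_index but no structural_index: ",
                 paste(which(func_no_struct), collapse = ", ")))
  }
  wm_func <- tab$tissue_class == "WM" & !is.na(tab$functional_index)
  if (any(wm_func)) {
    abort(paste0("WM region(s) with a functional_index in row(s) ",
                 paste(which(wm_func), collapse = ", ")))
  }
  class(tab) <- c("region_table", class(tab))
  tab
}

check_contiguous_index <- function(idx, what) {
  present <- idx[!is.na(idx)]
  if (length(present) == 0) return(invisible(NULL))
  if (anyDuplicated(present)) {
    dup <- unique(present[duplicated(present)])
    abort(paste0("duplicated ", what, ": ", paste(dup, collapse = ", ")))
  }
  if (!setequal(present, seq_len(length(present)))) {
    abort(paste0(what, " values must form a contiguous 1..",
                 length(present), " range"))
  }
  invisible(NULL)
}

#' Derive network node sets from a region table
#'
#' `structural_nodes()` returns one node per region carrying a structural
#' index (all 76 parcellation regions in the packaged table);
#' `functional_nodes()` returns the gray-matter subset carrying a functional
#' index (54 in the packaged table). Node ids are 0-based and ordered by the
#' table's 1-based index, fixing the row/column convention of every adjacency
#' matrix built downstream.
#'
#' @param tab A validated `region_table`.
#' @return A tibble with columns `node_id` (0-based), `region_name`,
#'   `hemisphere`, `source_index` (the table's 1-based index) and `label`.
#' @examples
#' tab <- read_region_table(example_region_table_path())
#' nrow(structural_nodes(tab))  # 76
#' nrow(functional_nodes(tab))  # 54
#' @export
structural_nodes <- function(tab) {
  node_set(tab, "structural_index")
}

#' @rdname structural_nodes
#' @export
functional_nodes <- function(tab) {
  node_set(tab, "functional_index")
}

node_set <- function(tab, index_col) {
  tab <- validate_region_table(tab)
  keep <- !is.na(tab[[index_col]])
  if (!any(keep)) {
    abort(paste0("no rows carry a ", index_col))
  }
  out <- tab[keep, ]
  out <- out[order(out[[index_col]]), ]
  tibble(
    node_id = seq_len(nrow(out)) - 1L,
    region_name = out$region_name,
    hemisphere = out$hemisphere,
    source_index = as.integer(out[[index_col]]),
    label = node_label(out$hemisphere, out$region_name)
  )
}

node_label <- function(hemisphere, region_name) {
  prefix <- c(right = "R", left = "L", midline = "M")[hemisphere]
  paste(prefix, region_name)
}
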