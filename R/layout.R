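# Physical slide layout: three identical 8x8 subarrays. Each subarray holds
# 56 gene CpG-island probes, 3 positive controls (full signal in both
# channels), 2 hybridization controls (nonspecific binding reference for the
# informativeness filter) and 3 empty spots (background reference).

.N_SUBARRAYS <- 3L
.GRID <- c(8L, 8L)
.N_GENE_SPOTS <- 56L

# fixed within-subarray positions (row-major index, 1..64) for control spots;
# gene probes fill the remaining positions in probe order
.POS_CTRL_IDX <- c(1L, 28L, 64L)
.HYB_CTRL_IDX <- c(9L, 56L)
.EMPTY_IDX <- c(17L, 40L, 61L)

#' Default MethDet-style array layout
#'
#' Builds the spot-role map of the default slide: 3 identical 8x8 subarrays,
#' each carrying 56 gene probes, 3 positive controls, 2 hybridization
#' controls and 3 empty background spots (64 spots per subarray, 192 total).
#'
#' @param genes Character vector of probe (gene) names placed on each
#'   subarray, length 56 at most. Defaults to the 21 screened genes plus
#'   placeholder null probes filling the grid.
#' @return A tibble with one row per spot and columns `subarray`, `row`,
#'   `col` (0-based), `role` (`"gene_probe"`, `"positive_control"`,
#'   `"hybridization_control"`, `"empty"`) and `gene_id` (`NA` for
#'   non-gene spots).
#' @examples
#' layout <- default_layout()
#' dplyr::count(layout, role)
#' @export
default_layout <- function(genes = default_gene_set()) {
  genes <- as.character(genes)
  if (anyDuplicated(genes)) {
    abort("duplicated probe names in `genes`")
  }
  if (length(genes) > .N_GENE_SPOTS) {
    abort(sprintf(
      "layout holds %d gene probes per subarray, got %d",
      .N_GENE_SPOTS, length(genes)
    ))
  }
  if (length(genes) < .N_GENE_SPOTS) {
    genes <- c(genes, null_probe_names(.N_GENE_SPOTS - length(genes),
      existing = genes
    ))
  }
  n_cell <- prod(.GRID)
  role <- rep("gene_probe", n_cell)
  role[.POS_CTRL_IDX] <- "positive_control"
  role[.HYB_CTRL_IDX] <- "hybridization_control"
  role[.EMPTY_IDX] <- "empty"
  gene_id <- rep(NA_character_, n_cell)
  gene_id[role == "gene_probe"] <- genes
  one <- tibble(
    row = rep(0:(.GRID[1] - 1L), each = .GRID[2]),
    col = rep(0:(.GRID[2] - 1L), times = .GRID[1]),
    role = role,
    gene_id = gene_id
  )
  bind_rows(lapply(0:(.N_SUBARRAYS - 1L), function(b) {
    mutate(one, subarray = b, .before = 1L)
  }))
}

#' Default probe set for the 56-spot layout
#'
#' The 21 genes of the published differential screen followed by placeholder
#' null probes (`NP_01`, ...) filling the 56 gene positions. The identities
#' of the remaining probes on the original array are not public, so null
#' placeholders stand in for them.
#'
#' @return Character vector of length 56.
#' @export
default_gene_set <- function() {
  screened <- default_effect_table()$gene_id
  c(screened, null_probe_names(.N_GENE_SPOTS - length(screened), screened))
}

null_probe_names <- function(n, existing = character()) {
  if (n <= 0L) {
    return(character())
  }
  nm <- sprintf("NP_%02d", seq_len(n))
  if (any(nm %in% existing)) abort("null probe name collision")
  nm
}
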