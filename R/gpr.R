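# GenePix-results-like dialect: tab-delimited, header row, one row per spot.
# Columns: Block (1-based subarray), Row, Column (1-based grid), Name (gene
# id or role tag), ID, F635 Median / B635 Median (control channel, Cy5,
# mock-digested), F532 Median / B532 Median (test channel, Cy3, digested),
# Flags (0 = ok, -50 = dropout). Columns are resolved by name, not position.

.GPR_COLS <- c(
  "Block", "Row", "Column", "Name", "ID",
  "F635 Median", "B635 Median", "F532 Median", "B532 Median", "Flags"
)

.ROLE_TAG <- c(
  positive_control = "POS_CTRL",
  hybridization_control = "HYB_CTRL",
  empty = "EMPTY"
)

#' Write one sample's spot table as a GPR-dialect file
#'
#' @param spots Spot tibble for a single sample (as produced by
#'   [simulate_sample_array()] or one sample of a cohort's `spots`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gpr <- function(spots, path) {
  nm <- ifelse(spots$role == "gene_probe", spots$gene_id,
    .ROLE_TAG[spots$role]
  )
  out <- tibble(
    Block = spots$subarray + 1L,
    Row = spots$row + 1L,
    Column = spots$col + 1L,
    Name = nm,
    ID = nm,
    "F635 Median" = spots$fg_control,
    "B635 Median" = spots$bg_control,
    "F532 Median" = spots$fg_test,
    "B532 Median" = spots$bg_test,
    Flags = ifelse(spots$flag == "dropout", -50L, 0L)
  )
  write_tsv(out, path)
  invisible(path)
}

#' Read a GPR-dialect spot file
#'
#' Parses a tab-delimited GenePix-results-like file into a spot tibble,
#' validating every position against the slide layout. Columns are matched
#' by header name so column order is free.
#'
#' @param path File path.
#' @param layout Slide layout the file must conform to
#'   (default [default_layout()]).
#' @return A spot tibble with the same columns as
#'   [simulate_sample_array()].
#' @export
read_gpr <- function(path, layout = default_layout()) {
  if (!file.exists(path)) abort(paste("no such file:", path))
  raw <- suppressWarnings(read_tsv(path,
    col_types = cols(.default = col_character()),
    progress = FALSE, show_col_types = FALSE
  ))
  missing_cols <- setdiff(.GPR_COLS, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "parse error in ", path, ": missing column(s) ",
      toString(missing_cols)
    ))
  }
  num_cols <- setdiff(.GPR_COLS, c("Name", "ID"))
  for (cc in num_cols) {
    v <- suppressWarnings(as.numeric(raw[[cc]]))
    if (anyNA(v)) {
      line <- (which(is.na(v))[1]) + 1L # +1 for the header row
      abort(sprintf(
        "parse error in %s, line %d: non-numeric value in column '%s'",
        path, line, cc
      ))
    }
    raw[[cc]] <- v
  }
  if (nrow(raw) != nrow(layout)) {
    abort(sprintf(
      "parse error in %s: expected %d spots, found %d",
      path, nrow(layout), nrow(raw)
    ))
  }
  spots <- tibble(
    subarray = as.integer(raw$Block) - 1L,
    row = as.integer(raw$Row) - 1L,
    col = as.integer(raw$Column) - 1L,
    name = raw$Name,
    fg_test = raw$`F532 Median`,
    bg_test = raw$`B532 Median`,
    fg_control = raw$`F635 Median`,
    bg_control = raw$`B635 Median`,
    flag = ifelse(raw$Flags < 0, "dropout", "ok")
  )
  merged <- left_join(spots, layout,
    by = c("subarray", "row", "col")
  )
  if (anyNA(merged$role)) {
    line <- which(is.na(merged$role))[1]
    abort(sprintf(
      "parse error in %s, line %d: position outside layout", path, line + 1L
    ))
  }
  if (anyDuplicated(merged[c("subarray", "row", "col")])) {
    abort(paste("parse error in", path, ": duplicated spot position"))
  }
  merged %>%
    select(all_of(c(
      "subarray", "row", "col", "role", "gene_id",
      "fg_test", "bg_test", "fg_control", "bg_control", "flag"
    )))
}

#' Write a simulated cohort to disk
#'
#' Emits one GPR-dialect file per sample (`<sample_id>.gpr`), a two-column
#' label table `labels.tsv` and the generating ground truth `truth.tsv`.
#'
#' @param cohort A `meth_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "meth_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (sid in cohort$samples$sample_id) {
    write_gpr(
      cohort$spots[cohort$spots$sample_id == sid, , drop = FALSE],
      file.path(dir, paste0(sid, ".gpr"))
    )
  }
  write_tsv(cohort$samples, file.path(dir, "labels.tsv"))
  write_tsv(cohort$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Directory containing `<sample_id>.gpr` files and `labels.tsv`.
#' @param layout Slide layout to validate against.
#' @return A list of class `meth_cohort` (without latent ground truth unless
#'   `truth.tsv` is present).
#' @export
read_cohort <- function(dir, layout = default_layout()) {
  lab_path <- file.path(dir, "labels.tsv")
  if (!file.exists(lab_path)) abort(paste("no labels.tsv in", dir))
  samples <- read_tsv(lab_path,
    col_types = "cc", progress = FALSE,
    show_col_types = FALSE
  )
  spots <- bind_rows(lapply(samples$sample_id, function(sid) {
    arr <- read_gpr(file.path(dir, paste0(sid, ".gpr")), layout)
    mutate(arr, sample_id = sid, .before = 1L)
  }))
  truth <- NULL
  tpath <- file.path(dir, "truth.tsv")
  if (file.exists(tpath)) {
    truth <- read_tsv(tpath, progress = FALSE, show_col_types = FALSE)
  }
  structure(
    list(
      samples = samples, spots = spots, latent = NULL,
      truth = truth, layout = layout, config = NULL
    ),
    class = "meth_cohort"
  )
}
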