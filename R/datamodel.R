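#' Construct a secretome concentration matrix
#'
#' A secretome matrix holds multiplex bead-assay concentrations (pg/mL) of
#' cytokines/chemokines (rows) across explant samples (columns). Missing
#' measurements are stored as `NA`; zeros are legal and are floored at
#' `detection_floor` only inside [log_transform()].
#'
#' @param values Numeric matrix, cytokines x samples, with unique non-empty
#'   rownames (cytokine ids) and colnames (sample ids). Non-missing entries
#'   must be >= 0.
#' @param detection_floor Assay detection floor in pg/mL (> 0), used as the
#'   pseudocount when taking logs.
#' @return A `secretome_matrix`: a numeric matrix with a `detection_floor`
#'   attribute.
#' @export
secretome_matrix <- function(values, detection_floor = 1) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  .check_ids(rownames(values), "cytokine")
  .check_ids(colnames(values), "sample")
  if (!is.numeric(detection_floor) || length(detection_floor) != 1L ||
      is.na(detection_floor) || detection_floor <= 0) {
    stop("`detection_floor` must be a single positive number", call. = FALSE)
  }
  .check_nonnegative(values, "concentration")
  structure(values, detection_floor = as.numeric(detection_floor),
            class = c("secretome_matrix", "matrix", "array"))
}

#' Construct an immune-infiltrate table
#'
#' Per-sample abundances of immune cell populations (e.g. CD4, CD8, CD90.2,
#' TAM, monocytes, neutrophils, DC1/DC2, Treg) from flow cytometry or IHC.
#'
#' @param values Numeric matrix, populations x samples, values >= 0, unique
#'   rownames (population ids) and colnames (sample ids).
#' @param unit `"count"` or `"percent"`; recorded per table.
#' @return An `infiltrate_table`: a numeric matrix with a `unit` attribute.
#' @export
infiltrate_table <- function(values, unit = c("count", "percent")) {
  unit <- match.arg(unit)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  .check_ids(rownames(values), "population")
  .check_ids(colnames(values), "sample")
  .check_nonnegative(values, "abundance")
  structure(values, unit = unit,
            class = c("infiltrate_table", "matrix", "array"))
}

.check_ids <- function(ids, what) {
  if (is.null(ids) || any(!nzchar(ids)) || anyNA(ids)) {
    stop(sprintf("%s ids must be present and non-empty", what), call. = FALSE)
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop(sprintf("duplicate %s id(s): %s", what,
                 paste(dup, collapse = ", ")), call. = FALSE)
  }
  invisible(ids)
}

.check_nonnegative <- function(values, what) {
  bad <- which(!is.na(values) & values < 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("negative %s at row '%s', column '%s' (value %g)",
                 what, rownames(values)[bad[1, 1]],
                 colnames(values)[bad[1, 2]],
                 values[bad[1, 1], bad[1, 2]]), call. = FALSE)
  }
  invisible(values)
}

#' @export
print.secretome_matrix <- function(x, ...) {
  cat(sprintf("secretome_matrix: %d cytokines x %d samples (%d missing, detection floor %g pg/mL)\n",
              nrow(x), ncol(x), sum(is.na(x)), attr(x, "detection_floor")))
  invisible(x)
}

#' @export
print.infiltrate_table <- function(x, ...) {
  cat(sprintf("infiltrate_table: %d populations x %d samples (unit: %s)\n",
              nrow(x), ncol(x), attr(x, "unit")))
  invisible(x)
}

#' Cytokine and sample identifiers
#'
#' @param x A `secretome_matrix` or `infiltrate_table`.
#' @return Character vector of ids.
#' @export
cytokine_ids <- function(x) rownames(x)

#' @rdname cytokine_ids
#' @export
sample_ids <- function(x) colnames(x)

## ---- delimited-text I/O ----------------------------------------------------

# sep by file extension: .csv -> comma, anything else (.tsv/.txt/.tab) -> tab
.sep_for <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

# Read a numeric table with id column first and sample header row.
# Cells must be numeric or a missing token; anything else is reported by cell.
.read_numeric_table <- function(path, what, missing_tokens = c("", "NA")) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  raw <- utils::read.table(path, sep = .sep_for(path), header = TRUE,
                           check.names = FALSE, colClasses = "character",
                           row.names = NULL, quote = "\"", comment.char = "",
                           stringsAsFactors = FALSE, na.strings = NULL)
  if (ncol(raw) < 2L) stop("table needs an id column plus >= 1 sample column",
                           call. = FALSE)
  ids <- raw[[1L]]
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  out <- matrix(NA_real_, nrow(vals), ncol(vals),
                dimnames = list(ids, colnames(vals)))
  for (j in seq_len(ncol(vals))) {
    cell <- trimws(vals[, j])
    miss <- cell %in% missing_tokens
    num <- suppressWarnings(as.numeric(cell))
    bad <- !miss & is.na(num)
    if (any(bad)) {
      i <- which(bad)[1L]
      stop(sprintf("non-numeric %s value '%s' at row '%s', column '%s'",
                   what, cell[i], ids[i], colnames(vals)[j]), call. = FALSE)
    }
    num[miss] <- NA_real_
    out[, j] <- num
  }
  out
}

#' Read a secretome concentration table
#'
#' Reads a delimited text file (CSV or TSV, auto-detected by extension) whose
#' header row carries sample ids and whose first column carries cytokine ids.
#' Empty cells and `"NA"` are recorded as missing, never as zero.
#'
#' @param path Path to a CSV/TSV file.
#' @param detection_floor Detection floor in pg/mL, see [secretome_matrix()].
#' @param missing_tokens Cell values treated as missing.
#' @return A validated [secretome_matrix()].
#' @export
read_secretome <- function(path, detection_floor = 1,
                           missing_tokens = c("", "NA")) {
  secretome_matrix(.read_numeric_table(path, "concentration", missing_tokens),
                   detection_floor = detection_floor)
}

#' Read an immune-infiltrate table
#'
#' Same dialect as [read_secretome()]: header row of sample ids, first column
#' of population ids. All-zero samples are legal (a poorly infiltrated tumor).
#'
#' @inheritParams read_secretome
#' @param unit `"count"` or `"percent"`.
#' @return A validated [infiltrate_table()].
#' @export
read_infiltrates <- function(path, unit = c("count", "percent"),
                             missing_tokens = c("", "NA")) {
  infiltrate_table(.read_numeric_table(path, "abundance", missing_tokens),
                   unit = match.arg(unit))
}

#' Write a secretome or infiltrate table
#'
#' Writes the matrix with the id column first and `NA` as the missing token,
#' at full double precision (round-trips to >= 12 significant digits).
#'
#' @param x A `secretome_matrix` or `infiltrate_table`.
#' @param path Output path; `.csv` writes comma-separated, otherwise tabs.
#' @return `path`, invisibly.
#' @export
write_secretome <- function(x, path) {
  df <- data.frame(id = rownames(x), unclass(x), check.names = FALSE)
  utils::write.table(df, path, sep = .sep_for(path), na = "NA",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_secretome
#' @export
write_infiltrates <- write_secretome

#' Treatment vocabulary for sample metadata
#' @export
TREATMENTS <- c("untreated", "anti-PD1", "anti-CTLA4", "anti-OX40",
                "combination")

#' Validate a sample-metadata table
#'
#' Metadata links each explant fragment (sample) to its tumor model, the
#' animal the tumor came from (replicate fragments of one animal share an
#' `animal_id`), and its treatment arm.
#'
#' @param metadata A data.frame with columns `sample_id`, `tumor_model`,
#'   `animal_id`, `treatment`.
#' @param treatments Allowed treatment vocabulary.
#' @return The validated data.frame (character columns).
#' @export
sample_metadata <- function(metadata, treatments = TREATMENTS) {
  need <- c("sample_id", "tumor_model", "animal_id", "treatment")
  miss <- setdiff(need, names(metadata))
  if (length(miss)) {
    stop("metadata missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  metadata <- as.data.frame(metadata, stringsAsFactors = FALSE)
  for (nm in need) metadata[[nm]] <- as.character(metadata[[nm]])
  .check_ids(metadata$sample_id, "metadata sample")
  bad <- setdiff(unique(metadata$treatment), treatments)
  if (length(bad)) {
    stop("unknown treatment label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  metadata
}

#' Read a sample-metadata table
#'
#' @param path CSV/TSV file with columns `sample_id`, `tumor_model`,
#'   `animal_id`, `treatment`.
#' @inheritParams sample_metadata
#' @return A validated metadata data.frame.
#' @export
read_metadata <- function(path, treatments = TREATMENTS) {
  df <- utils::read.table(path, sep = .sep_for(path), header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "\"", comment.char = "")
  sample_metadata(df, treatments = treatments)
}

#' Read a protein-protein functional edge list
#'
#' Two or three tab-separated columns (`idA`, `idB`[, `score`]), compatible
#' with STRING exports. Self-loops are dropped with a warning; scores, when
#' present, must lie in [0, 1].
#'
#' @param path Path to a TSV (or CSV) edge list, with or without a header.
#' @return A data.frame with columns `from`, `to` and optionally `score`.
#' @export
read_edge_list <- function(path) {
  raw <- utils::read.table(path, sep = .sep_for(path), header = FALSE,
                           check.names = FALSE, colClasses = "character",
                           quote = "\"", comment.char = "",
                           stringsAsFactors = FALSE)
  if (!ncol(raw) %in% 2:3) {
    stop("edge list must have 2 or 3 columns (idA, idB[, score])",
         call. = FALSE)
  }
  # header detection: a 3rd-column value that is not numeric is a header row
  has_header <- FALSE
  if (ncol(raw) == 3L) {
    has_header <- is.na(suppressWarnings(as.numeric(raw[1L, 3L])))
  } else {
    has_header <- tolower(raw[1L, 1L]) %in%
      c("from", "ida", "node1", "protein1", "source")
  }
  if (has_header) raw <- raw[-1L, , drop = FALSE]
  out <- data.frame(from = raw[[1L]], to = raw[[2L]],
                    stringsAsFactors = FALSE)
  if (ncol(raw) == 3L) {
    score <- as.numeric(raw[[3L]])
    if (anyNA(score) || any(score < 0 | score > 1)) {
      stop("edge scores must be numeric in [0, 1]", call. = FALSE)
    }
    out$score <- score
  }
  loops <- out$from == out$to
  if (any(loops)) {
    warning(sprintf("dropped %d self-loop(s)", sum(loops)), call. = FALSE)
    out <- out[!loops, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

## ---- explant / tumor alignment --------------------------------------------

#' Map explant samples to their tumor's infiltrate record
#'
#' Infiltrates are measured once per tumor (animal) while the secretome is
#' measured per explant fragment, so the two tables are joined through the
#' metadata's `animal_id`: every fragment of one animal maps to that animal's
#' infiltrate record. Samples lacking metadata, or whose animal has no
#' infiltrate record, are reported as unmatched and excluded downstream.
#'
#' @param secretome A [secretome_matrix()].
#' @param infiltrates An [infiltrate_table()] whose sample ids are animal ids.
#' @param metadata A validated metadata data.frame ([sample_metadata()]).
#' @return A list with `mapping` (data.frame `sample_id`, `animal_id`,
#'   `infiltrate_id`, matched rows only) and `unmatched` (character vector).
#' @export
align_tables <- function(secretome, infiltrates, metadata) {
  metadata <- sample_metadata(metadata,
                              treatments = unique(metadata$treatment))
  sids <- sample_ids(secretome)
  hits <- match(sids, metadata$sample_id)
  # duplicate sample_ids already rejected by sample_metadata(); a sample
  # mapping to two infiltrate records cannot arise because infiltrate sample
  # ids are unique, so the remaining ambiguity is contradictory metadata rows
  animal <- metadata$animal_id[hits]
  inf_id <- ifelse(!is.na(animal) & animal %in% sample_ids(infiltrates),
                   animal, NA_character_)
  matched <- !is.na(inf_id)
  list(
    mapping = data.frame(sample_id = sids[matched],
                         animal_id = animal[matched],
                         infiltrate_id = inf_id[matched],
                         stringsAsFactors = FALSE),
    unmatched = sids[!matched]
  )
}

#' Aggregate explant fragments per animal
#'
#' Averages the replicate fragments of each animal (per cytokine, missing
#' values removed) so that per-tumor secretion can be paired with the
#' per-tumor infiltrate record.
#'
#' @param secretome A [secretome_matrix()].
#' @param metadata Validated metadata; only samples present in it are used.
#' @param fun Aggregator, `"mean"` (default) or `"median"`.
#' @param arm If non-`NULL`, restrict to samples of this treatment arm first.
#' @return A numeric matrix, cytokines x animals.
#' @export
aggregate_secretome <- function(secretome, metadata,
                                fun = c("mean", "median"), arm = NULL) {
  fun <- match.arg(fun)
  f <- if (fun == "mean") {
    function(v) mean(v, na.rm = TRUE)
  } else {
    function(v) stats::median(v, na.rm = TRUE)
  }
  md <- metadata[metadata$sample_id %in% sample_ids(secretome), , drop = FALSE]
  if (!is.null(arm)) md <- md[md$treatment == arm, , drop = FALSE]
  if (!nrow(md)) stop("no samples left to aggregate", call. = FALSE)
  animals <- unique(md$animal_id)
  out <- vapply(animals, function(a) {
    cols <- md$sample_id[md$animal_id == a]
    apply(unclass(secretome)[, cols, drop = FALSE], 1L, f)
  }, numeric(nrow(secretome)))
  out <- matrix(out, nrow = nrow(secretome),
                dimnames = list(cytokine_ids(secretome), animals))
  out[is.nan(out)] <- NA_real_
  out
}
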