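# TSV dialect is fixed throughout: tab separator, mandatory header, UTF-8,
# no quoting, LF endings -- so write(read(x)) round-trips byte-identically.

.read_tsv <- function(path, colClasses = "character") {
  utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                    comment.char = "", colClasses = colClasses,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

.write_tsv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con, sep = "\n")
  if (nrow(df)) {
    lines <- do.call(paste, c(lapply(df, as.character), sep = "\t"))
    writeLines(lines, con, sep = "\n")
  }
  invisible(path)
}

.input_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("dropout3d_input_error", "error")))
}

#' Read and validate a guide library TSV
#'
#' Expects a header with columns `guide_id`, `gene`, `spacer`, `category`.
#' Rejects duplicate guide ids, duplicate spacers (reporting the guide ids
#' that share them), non-ACGT or wrong-length spacers, unknown categories,
#' and control guides whose gene is not the `"CONTROL"` sentinel.
#'
#' @param path path to a tab-separated library file
#' @return a [GuideLibrary-class], rows in file order
#' @export
readGuideLibrary <- function(path) {
  df <- .read_tsv(path)
  need <- c("guide_id", "gene", "spacer", "category")
  miss <- setdiff(need, names(df))
  if (length(miss))
    .input_error("guide library is missing columns: ", paste(miss, collapse = ", "))
  lib <- tryCatch(GuideLibrary(df[need]), error = function(e)
    .input_error("invalid guide library (", path, "): ", conditionMessage(e)))
  lib
}

#' Write a guide library TSV
#' @param library a [GuideLibrary-class]
#' @param path output path
#' @export
writeGuideLibrary <- function(library, path) {
  .write_tsv(guideRecords(library), path)
}

#' Read a sample sheet TSV
#'
#' Columns: `sample_id`, `condition` ("2D"/"3D"), `day` (0/7/14),
#' `replicate` (positive integer).
#'
#' @param path path to a tab-separated sample sheet
#' @return data.frame sample sheet
#' @export
readSampleSheet <- function(path) {
  df <- .read_tsv(path)
  need <- c("sample_id", "condition", "day", "replicate")
  miss <- setdiff(need, names(df))
  if (length(miss))
    .input_error("sample sheet is missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    .input_error("duplicate sample_id in sample sheet")
  if (!all(df$condition %in% .CONDITIONS))
    .input_error("condition must be one of: ", paste(.CONDITIONS, collapse = ", "))
  day <- suppressWarnings(as.integer(df$day))
  rep <- suppressWarnings(as.integer(df$replicate))
  if (anyNA(day) || !all(day %in% c(0L, 7L, 14L)))
    .input_error("day must be 0, 7 or 14")
  if (anyNA(rep) || any(rep < 1L))
    .input_error("replicate must be a positive integer")
  key <- paste(df$condition, day, rep)
  if (anyDuplicated(key))
    .input_error("(condition, day, replicate) must be unique in the sample sheet")
  data.frame(sample_id = df$sample_id, condition = df$condition,
             day = day, replicate = rep, stringsAsFactors = FALSE)
}

#' Write a sample sheet TSV
#' @param design data.frame sample sheet
#' @param path output path
#' @export
writeSampleSheet <- function(design, path) {
  .write_tsv(design[c("sample_id", "condition", "day", "replicate")], path)
}

#' Read a guide-by-sample count table
#'
#' First column `guide_id`, one column per sample. Counts must be
#' non-negative integers; guides unknown to the library are rejected, and
#' library guides missing from the file are an error unless
#' `fillMissing = TRUE` zero-fills them (reported via a warning either way).
#' Sample columns must all be declared in the design.
#'
#' @param path path to a tab-separated count file
#' @param library a [GuideLibrary-class]
#' @param design data.frame sample sheet (see [readSampleSheet()])
#' @param fillMissing zero-fill guides absent from the file instead of
#'   erroring (default FALSE: silent zero-fill can mask quantification bugs)
#' @return a [ScreenExperiment-class] with rows in library order
#' @export
readCounts <- function(path, library, design, fillMissing = FALSE) {
  df <- .read_tsv(path)
  if (names(df)[1] != "guide_id")
    .input_error("count table must have 'guide_id' as its first column")
  sample_ids <- names(df)[-1]
  unknown_samples <- setdiff(sample_ids, design$sample_id)
  if (length(unknown_samples))
    .input_error("count columns absent from the design: ",
                 paste(unknown_samples, collapse = ", "))
  if (anyDuplicated(df$guide_id))
    .input_error("duplicate guide_id in count table: ",
                 paste(unique(df$guide_id[duplicated(df$guide_id)]), collapse = ", "))
  extra <- setdiff(df$guide_id, guideIds(library))
  if (length(extra))
    .input_error("count table contains guides not in the library: ",
                 paste(utils::head(extra, 5L), collapse = ", "))
  num <- df[-1]
  for (j in seq_along(num)) {
    v <- suppressWarnings(as.numeric(num[[j]]))
    bad <- which(is.na(v) | v < 0 | v != round(v))
    if (length(bad))
      .input_error("count for guide '", df$guide_id[bad[1]], "', sample '",
                   sample_ids[j], "' is not a non-negative integer: ",
                   num[[j]][bad[1]])
    num[[j]] <- as.integer(round(v))
  }
  mat <- as.matrix(num)
  rownames(mat) <- df$guide_id
  missing <- setdiff(guideIds(library), df$guide_id)
  if (length(missing)) {
    if (!fillMissing)
      .input_error("library guides missing from count table: ",
                   paste(utils::head(missing, 10L), collapse = ", "),
                   if (length(missing) > 10L) sprintf(" (and %d more)", length(missing) - 10L) else "")
    warning(sprintf("zero-filling %d library guides missing from %s",
                    length(missing), path), call. = FALSE)
    fill <- matrix(0L, nrow = length(missing), ncol = ncol(mat),
                   dimnames = list(missing, colnames(mat)))
    mat <- rbind(mat, fill)
  }
  mat <- mat[guideIds(library), , drop = FALSE]
  ScreenExperiment(mat, library, design[design$sample_id %in% sample_ids, , drop = FALSE])
}

#' Write the count matrix of a ScreenExperiment as canonical TSV
#'
#' Guide order is library order; columns are tab-separated with LF endings,
#' so a read/write round-trip of a canonical file is byte-identical.
#'
#' @param se a [ScreenExperiment-class]
#' @param path output path
#' @export
writeCounts <- function(se, path) {
  mat <- counts(se)
  df <- data.frame(guide_id = rownames(mat), as.data.frame(mat),
                   check.names = FALSE, stringsAsFactors = FALSE)
  .write_tsv(df, path)
}

#' Enumerate endpoint-vs-baseline comparisons of a design
#'
#' The full two-condition, day 0/7/14 design yields exactly four
#' comparisons: each condition's day 7 and day 14 against its day 0.
#'
#' @param design data.frame sample sheet or a [ScreenExperiment-class]
#' @param computableOnly drop comparisons lacking a baseline or endpoint
#' @return data.frame with condition, day, label (e.g. "3D_D14_vs_D0")
#' @export
screenComparisons <- function(design, computableOnly = TRUE) {
  if (is(design, "ScreenExperiment")) design <- screenDesign(design)
  grid <- expand.grid(condition = .CONDITIONS, day = c(7L, 14L),
                      stringsAsFactors = FALSE)
  grid$label <- sprintf("%s_D%d_vs_D0", grid$condition, grid$day)
  if (computableOnly) {
    ok <- vapply(seq_len(nrow(grid)), function(i) {
      cond <- grid$condition[i]; day <- grid$day[i]
      any(design$condition == cond & design$day == 0L) &&
        any(design$condition == cond & design$day == day)
    }, logical(1))
    grid <- grid[ok, , drop = FALSE]
  }
  grid <- grid[order(grid$condition, grid$day), , drop = FALSE]
  rownames(grid) <- NULL
  grid
}

#' Validate a screen design against its counts
#'
#' Report-only: lists the comparisons that are computable (a condition's
#' baseline and endpoint both present), replicate counts for each
#' (condition, day) cell, and warnings for missing cells.
#'
#' @param design data.frame sample sheet or a [ScreenExperiment-class]
#' @param counts optional count matrix checked for dimension agreement
#' @return a `designReport` list with elements `comparisons`,
#'   `replicates`, `warnings`
#' @export
validateDesign <- function(design, counts = NULL) {
  if (is(design, "ScreenExperiment")) {
    if (is.null(counts)) counts <- BiocGenerics::counts(design)
    design <- screenDesign(design)
  }
  warnings <- character()
  if (!is.null(counts) && ncol(counts) != nrow(design))
    warnings <- c(warnings, sprintf(
      "count matrix has %d samples but design has %d", ncol(counts), nrow(design)))
  comp <- screenComparisons(design, computableOnly = TRUE)
  all_comp <- screenComparisons(design, computableOnly = FALSE)
  missing <- setdiff(all_comp$label, comp$label)
  if (nrow(design) && length(missing))
    warnings <- c(warnings, paste0("comparison not computable: ",
                                   paste(missing, collapse = ", ")))
  reps <- if (nrow(design)) {
    agg <- stats::aggregate(list(n_replicates = design$replicate),
                            by = list(condition = design$condition, day = design$day),
                            FUN = length)
    agg[order(agg$condition, agg$day), , drop = FALSE]
  } else {
    data.frame(condition = character(), day = integer(), n_replicates = integer())
  }
  rownames(reps) <- NULL
  out <- list(comparisons = comp, replicates = reps, warnings = warnings)
  class(out) <- "designReport"
  out
}

#' @export
print.designReport <- function(x, ...) {
  cat("Design report:", nrow(x$comparisons), "computable comparison(s)\n")
  if (nrow(x$comparisons)) cat(" ", paste(x$comparisons$label, collapse = ", "), "\n")
  if (length(x$warnings)) cat("warnings:\n", paste(" -", x$warnings, collapse = "\n"), "\n")
  invisible(x)
}
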