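# Exact-match guide quantification from FASTQ. Deliberately alignment-free:
# 17-18-mer exact matching with an optional shift window is deterministic and
# sufficient to assign amplicon reads to a validated library with unique
# spacers; mismatched or ambiguous reads stay unassigned and are reported.

#' Matching configuration for FASTQ quantification
#'
#' @param offset 0-based start position of the spacer within the read, or
#'   `NULL` for SCAN mode (try every position, left to right).
#' @param window non-negative shift tolerance around `offset`; positions
#'   `offset - window` .. `offset + window` are tried in ascending order,
#'   at each position the 18-mer before the 17-mer, first hit wins.
#' @param minReadsReported QC-only threshold: guides below it are flagged in
#'   the QC summary, never dropped.
#' @return a `matchConfig` list
#' @export
matchConfig <- function(offset = NULL, window = 0L, minReadsReported = 0L) {
  if (!is.null(offset)) {
    offset <- as.integer(offset)
    if (is.na(offset) || offset < 0L) .input_error("offset must be >= 0")
  }
  window <- as.integer(window)
  if (is.na(window) || window < 0L) .input_error("window must be >= 0")
  structure(list(offset = offset, window = window,
                 minReadsReported = as.integer(minReadsReported)),
            class = "matchConfig")
}

#' Build an exact-match spacer index
#'
#' One hash per spacer length (17 and 18 nt), mapping upper-case spacer to
#' guide id. Library validation has already guaranteed spacer uniqueness.
#'
#' @param library a [GuideLibrary-class]
#' @return a `spacerIndex` object
#' @export
buildSpacerIndex <- function(library) {
  rec <- guideRecords(library)
  idx <- list()
  for (L in c(18L, 17L)) {
    sel <- nchar(rec$spacer) == L
    env <- new.env(hash = TRUE, parent = emptyenv(), size = max(2L, sum(sel)))
    if (any(sel))
      for (i in which(sel)) assign(rec$spacer[i], rec$guide_id[i], envir = env)
    idx[[as.character(L)]] <- env
  }
  structure(list(by_length = idx, guide_ids = rec$guide_id,
                 lengths = sort(unique(nchar(rec$spacer)), decreasing = TRUE)),
            class = "spacerIndex")
}

#' Look up spacers in the index
#' @param index a `spacerIndex`
#' @param spacers character vector of candidate sequences (any case)
#' @return guide ids, NA where unmatched
#' @export
lookupSpacer <- function(index, spacers) {
  spacers <- toupper(spacers)
  out <- rep(NA_character_, length(spacers))
  for (L in index$lengths) {
    sel <- which(is.na(out) & nchar(spacers) == L)
    if (length(sel)) {
      hits <- unlist(mget(spacers[sel], envir = index$by_length[[as.character(L)]],
                          ifnotfound = NA_character_), use.names = FALSE)
      out[sel] <- hits
    }
  }
  out
}

.open_sequence_file <- function(path) {
  magic <- readBin(path, "raw", n = 2L)
  if (length(magic) == 2L && magic[1] == as.raw(0x1f) && magic[2] == as.raw(0x8b))
    gzfile(path, open = "rt") else file(path, open = "rt")
}

.fastq_sequences <- function(path) {
  con <- .open_sequence_file(path)
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  n <- length(lines)
  if (n == 0L) return(character())
  if (n %% 4L != 0L)
    .input_error("malformed FASTQ (", path, "): truncated record ", n %/% 4L + 1L)
  head_ok <- startsWith(lines[seq(1L, n, by = 4L)], "@")
  sep_ok <- startsWith(lines[seq(3L, n, by = 4L)], "+")
  if (!all(head_ok) || !all(sep_ok)) {
    bad <- min(c(which(!head_ok), which(!sep_ok)))
    .input_error("malformed FASTQ (", path, "): record ", bad,
                 " lacks the @/+ quartet structure")
  }
  lines[seq(2L, n, by = 4L)]
}

#' Count guides in a FASTQ file by exact spacer matching
#'
#' Each read is assigned to at most one guide: at each candidate position
#' (the configured offset +/- window, or every position in SCAN mode,
#' ascending), the 18-mer substring is looked up first, then the 17-mer;
#' the first hit wins. Matching is case-insensitive; reads too short for a
#' position are simply not matched there. Assigned + unassigned always
#' equals the number of reads.
#'
#' @param fastq path to a FASTQ file, plain or gzipped (sniffed by magic bytes)
#' @param index a `spacerIndex` from [buildSpacerIndex()]
#' @param config a [matchConfig()]
#' @param library optional [GuideLibrary-class] to add per-category totals
#'   to the QC summary
#' @return list with `counts` (named integer vector over all guides) and
#'   `qc` (reads, assigned, unassigned, assignment_rate, low_count_guides,
#'   and per-category totals when `library` is given)
#' @export
countGuides <- function(fastq, index, config = matchConfig(), library = NULL) {
  seqs <- toupper(.fastq_sequences(fastq))
  nreads <- length(seqs)
  assigned <- rep(NA_character_, nreads)
  if (nreads) {
    maxlen <- max(nchar(seqs))
    positions <- if (is.null(config$offset)) {
      seq_len(max(0L, maxlen - 17L + 1L))               # SCAN: every start
    } else {
      p0 <- config$offset + 1L                           # 0-based -> 1-based
      seq(max(1L, p0 - config$window), p0 + config$window)
    }
    lens <- nchar(seqs)
    for (p in positions) {
      for (L in c(18L, 17L)) {
        todo <- which(is.na(assigned) & lens >= p + L - 1L)
        if (!length(todo)) next
        hits <- lookupSpacer(index, substr(seqs[todo], p, p + L - 1L))
        assigned[todo[!is.na(hits)]] <- hits[!is.na(hits)]
      }
      if (!anyNA(assigned)) break
    }
  }
  counts <- table(factor(assigned, levels = index$guide_ids))
  counts <- stats::setNames(as.integer(counts), index$guide_ids)
  n_assigned <- sum(counts)
  qc <- list(reads = nreads, assigned = n_assigned,
             unassigned = nreads - n_assigned,
             assignment_rate = if (nreads) n_assigned / nreads else NA_real_,
             low_count_guides = names(counts)[counts < config$minReadsReported])
  if (!is.null(library)) {
    rec <- guideRecords(library)
    cat_of <- rec$category[match(names(counts), rec$guide_id)]
    qc$category_totals <- vapply(split(counts, cat_of), sum, numeric(1))
  }
  list(counts = counts, qc = qc)
}

#' Quantify several FASTQ files into a ScreenExperiment
#'
#' @param fastqs named character vector, `sample_id = path`
#' @param library a [GuideLibrary-class]
#' @param design data.frame sample sheet covering the sample ids
#' @param config a [matchConfig()]
#' @return list with `se` (a [ScreenExperiment-class]) and `qc`
#'   (per-sample QC summaries)
#' @export
countScreen <- function(fastqs, library, design, config = matchConfig()) {
  if (is.null(names(fastqs)) || any(!nzchar(names(fastqs))))
    .input_error("fastqs must be a named vector: sample_id = path")
  index <- buildSpacerIndex(library)
  res <- lapply(fastqs, countGuides, index = index, config = config,
                library = library)
  mat <- vapply(res, function(r) r$counts, integer(length(guideIds(library))))
  dimnames(mat) <- list(guideIds(library), names(fastqs))
  list(se = ScreenExperiment(mat, library,
                             design[design$sample_id %in% names(fastqs), , drop = FALSE]),
       qc = lapply(res, `[[`, "qc"))
}
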