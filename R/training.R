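# Training pipeline: genome annotation files -> architectures -> unique set
# -> n-gram counts -> first-order model.

#' Describe the column layout of an annotation file
#'
#' Annotation files are tab-separated, one domain assignment per line, in the
#' style of SUPERFAMILY genome self-assignment downloads: a genome (species)
#' identifier, the protein/sequence identifier the domain was found in, the
#' matched region in amino-acid coordinates, and the superfamily identifier.
#' The dialect maps those fields to column positions so other layouts can be
#' read without rewriting the file.
#'
#' @param genome_id,protein_id,region,superfamily_id,family_id 1-based column
#'   indices. `family_id` is optional (`NA` to ignore). `region` holds
#'   `"start-end"`; alternatively give `region_start`/`region_end` as two
#'   separate columns and leave `region = NA`.
#' @param region_start,region_end Column indices used when start and end are
#'   separate columns.
#' @return A named list of class `annotation_dialect`.
#' @export
annotation_dialect <- function(genome_id = 1L, protein_id = 2L, region = 3L,
                               superfamily_id = 4L, family_id = NA_integer_,
                               region_start = NA_integer_,
                               region_end = NA_integer_) {
  if (is.na(region) && (is.na(region_start) || is.na(region_end)))
    stop("either region or both region_start and region_end must be given")
  structure(list(genome_id = genome_id, protein_id = protein_id,
                 region = region, superfamily_id = superfamily_id,
                 family_id = family_id, region_start = region_start,
                 region_end = region_end),
            class = "annotation_dialect")
}

#' Parse a domain annotation file
#'
#' Reads a tab-separated annotation file into one record per domain
#' assignment. Malformed lines (too few columns, unparsable region,
#' start > end, empty superfamily id) are collected and reported with their
#' line numbers; in strict mode any malformed line aborts the parse.
#'
#' @param file Path to the annotation file.
#' @param dialect An [annotation_dialect()].
#' @param strict If `TRUE`, error on the first malformed line instead of
#'   skipping it with a warning.
#' @return A data frame with columns `genome_id`, `protein_id`,
#'   `region_start`, `region_end`, `family_id`, `superfamily_id`, plus a
#'   `"skipped"` attribute (data frame of line numbers and reasons).
#' @examples
#' f <- system.file("extdata", "synthetic_annotations.tsv",
#'                  package = "darchsim")
#' records <- parse_annotations(f)
#' assemble_architectures(records)
#' @export
parse_annotations <- function(file, dialect = annotation_dialect(),
                              strict = FALSE) {
  if (!file.exists(file)) stop("annotation file not found: ", file)
  lines <- readLines(file, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    warning("no annotation records in ", file)
    return(empty_annotation_frame())
  }

  fields <- strsplit(lines, "\t", fixed = TRUE)
  need <- max(dialect$genome_id, dialect$protein_id, dialect$superfamily_id,
              dialect$region, dialect$region_start, dialect$region_end,
              na.rm = TRUE)

  rows <- vector("list", length(lines))
  bad <- list()
  for (i in seq_along(lines)) {
    f <- fields[[i]]
    reason <- NULL
    if (length(f) < need) {
      reason <- "too few columns"
    } else {
      if (!is.na(dialect$region)) {
        m <- regmatches(f[dialect$region],
                        regexec("^\\s*(\\d+)\\s*-\\s*(\\d+)\\s*$",
                                f[dialect$region]))[[1]]
        if (length(m) != 3L) {
          reason <- paste0("unparsable region '", f[dialect$region], "'")
        } else {
          rs <- as.integer(m[2]); re <- as.integer(m[3])
        }
      } else {
        rs <- suppressWarnings(as.integer(f[dialect$region_start]))
        re <- suppressWarnings(as.integer(f[dialect$region_end]))
        if (is.na(rs) || is.na(re)) reason <- "unparsable region columns"
      }
      if (is.null(reason) && rs > re) reason <- "region start > end"
      if (is.null(reason) && !nzchar(trimws(f[dialect$superfamily_id])))
        reason <- "empty superfamily id"
    }
    if (!is.null(reason)) {
      if (strict)
        stop("line ", lineno[i], ": ", reason)
      bad[[length(bad) + 1L]] <- data.frame(line = lineno[i], reason = reason)
      next
    }
    rows[[i]] <- data.frame(
      genome_id = trimws(f[dialect$genome_id]),
      protein_id = trimws(f[dialect$protein_id]),
      region_start = rs, region_end = re,
      family_id = if (is.na(dialect$family_id)) NA_character_
                  else trimws(f[dialect$family_id]),
      superfamily_id = trimws(f[dialect$superfamily_id]),
      stringsAsFactors = FALSE
    )
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows)) do.call(rbind, rows) else empty_annotation_frame()
  skipped <- if (length(bad)) do.call(rbind, bad)
             else data.frame(line = integer(), reason = character())
  if (nrow(skipped))
    warning(nrow(skipped), " malformed line(s) skipped in ", file,
            " (first: line ", skipped$line[1], ", ", skipped$reason[1], ")")
  attr(out, "skipped") <- skipped
  out
}

empty_annotation_frame <- function() {
  data.frame(genome_id = character(), protein_id = character(),
             region_start = integer(), region_end = integer(),
             family_id = character(), superfamily_id = character(),
             stringsAsFactors = FALSE)
}

#' Assemble per-protein domain architectures from annotation records
#'
#' Domains on each protein are ordered by ascending region start (ties broken
#' by ascending region end, then superfamily id, for determinism); the
#' resulting N- to C-terminal token order is the protein's architecture.
#' Overlapping domain regions are kept as annotated, ordered by start; the
#' number of overlapping pairs is reported in the `"n_overlaps"` attribute.
#'
#' @param records Data frame from [parse_annotations()] (possibly several
#'   genomes row-bound together).
#' @return A named list of architectures (character vectors), keyed by
#'   `genome_id|protein_id`. Proteins with zero assignments do not appear.
#' @export
assemble_architectures <- function(records) {
  if (nrow(records) == 0L) return(structure(list(), names = character()))
  key <- paste(records$genome_id, records$protein_id, sep = "|")
  ord <- order(key, records$region_start, records$region_end,
               records$superfamily_id, method = "radix")
  records <- records[ord, , drop = FALSE]
  key <- key[ord]
  # overlap: a domain starting before the previous one on the same protein ends
  same <- c(FALSE, key[-1L] == key[-length(key)])
  prev_end <- c(NA_integer_, records$region_end[-nrow(records)])
  n_overlaps <- sum(same & records$region_start <= prev_end, na.rm = TRUE)
  archs <- split(records$superfamily_id, factor(key, levels = unique(key)))
  structure(archs, n_overlaps = n_overlaps)
}

#' Deduplicate a list of architectures
#'
#' Exact-sequence deduplication of architectures, removing the
#' over-representation of bigrams caused by gene duplication. Output order is
#' deterministic (lexicographic on the token sequence).
#'
#' @param archs List of architectures (character vectors); names are dropped.
#' @return Unnamed list of distinct architectures in lexicographic order.
#' @export
unique_architectures <- function(archs) {
  if (length(archs) == 0L) return(list())
  keys <- vapply(archs, paste, character(1), collapse = " ")
  unname(lapply(strsplit(sort(unique(keys)), " ", fixed = TRUE), identity))
}

#' Build a training corpus from annotation files
#'
#' Convenience wrapper for the whole training pipeline: parse one or more
#' annotation files, assemble architectures, pool across genomes, take the
#' unique set and count n-grams.
#'
#' @param files Character vector of annotation file paths.
#' @param dialect An [annotation_dialect()].
#' @param strict Passed to [parse_annotations()].
#' @return An object of class `training_corpus`: `unique_architectures`
#'   (list), `alphabet`, `counts` ([count_ngrams()] tables), `provenance`
#'   (the input paths) and `n_proteins`.
#' @export
training_corpus <- function(files, dialect = annotation_dialect(),
                            strict = FALSE) {
  records <- do.call(rbind, lapply(files, parse_annotations,
                                   dialect = dialect, strict = strict))
  archs <- assemble_architectures(records)
  corpus_from_architectures(unique_architectures(archs),
                            provenance = files, n_proteins = length(archs))
}

#' Build a training corpus from a list of architectures
#'
#' @param archs List of architectures; deduplicated internally.
#' @param provenance Optional character vector recording the source.
#' @param n_proteins Number of proteins before deduplication (informational).
#' @return A `training_corpus`.
#' @export
corpus_from_architectures <- function(archs, provenance = character(),
                                      n_proteins = length(archs)) {
  uniq <- unique_architectures(archs)
  if (length(uniq) == 0L) stop("no architectures in corpus")
  counts <- count_ngrams(uniq)
  structure(
    list(unique_architectures = uniq, alphabet = counts$alphabet,
         counts = counts, provenance = provenance, n_proteins = n_proteins),
    class = "training_corpus"
  )
}

#' @export
print.training_corpus <- function(x, ...) {
  lens <- lengths(x$unique_architectures)
  cat("Training corpus:", length(x$unique_architectures), "unique DAs,",
      length(x$alphabet), "domain superfamilies\n")
  cat("  mean DA length", round(mean(lens), 2), "| median", median(lens), "\n")
  if (length(x$provenance))
    cat("  sources:", paste(x$provenance, collapse = ", "), "\n")
  invisible(x)
}

#' @importFrom stats median
NULL
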