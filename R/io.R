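# Plain-text formats: the one-architecture-per-line DA format and the JSON
# model artifact. The model artifact stores counts (not probabilities) so the
# pseudocount can be changed without retraining.

#' Read a plain DA file
#'
#' One architecture per line, whitespace-separated superfamily tokens;
#' `#` starts a comment line; blank lines are ignored.
#'
#' @param file Path.
#' @return List of architectures (character vectors).
#' @export
read_da_file <- function(file) {
  if (!file.exists(file)) stop("DA file not found: ", file)
  lines <- readLines(file, warn = FALSE, encoding = "UTF-8")
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  lapply(strsplit(trimws(lines), "\\s+"), identity)
}

#' Write architectures to a plain DA file
#'
#' @param archs List of architectures, or a `training_corpus` (its unique
#'   architectures are written).
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_da_file <- function(archs, file) {
  if (inherits(archs, "training_corpus")) archs <- archs$unique_architectures
  lapply(archs, assert_architecture)
  writeLines(vapply(archs, paste, character(1), collapse = " "), file,
             useBytes = TRUE)
  invisible(file)
}

#' Write a model to JSON
#'
#' For trained models the artifact holds the alphabet, the pseudocount, the
#' number of unique training DAs, monogram counts and the sparse nonzero
#' bigram counts (`prev`, `next`, `count` triplets; the NULL terminus is
#' written as the sentinel string) -- counts rather than probabilities, so
#' the pseudocount can be changed without retraining. Models built directly
#' from a probability table (e.g. synthetic ground truths) are written with
#' their dense probability rows instead.
#'
#' @param model A `first_order_model`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_model_json <- function(model, file) {
  if (!inherits(model, "first_order_model")) stop("not a first_order_model")
  if (is.null(model$counts)) {
    obj <- list(
      format = "darchsim-model", version = 1L, kind = "probabilities",
      null_token = .NULL_TOKEN, alphabet = model$alphabet, k = model$k,
      prob = apply(model$prob, 1L, identity, simplify = FALSE)
    )
    jsonlite::write_json(obj, file, auto_unbox = TRUE, digits = NA)
    return(invisible(file))
  }
  big <- model$counts$bigram
  nz <- which(big > 0L, arr.ind = TRUE)
  obj <- list(
    format = "darchsim-model",
    version = 1L,
    kind = "counts",
    null_token = .NULL_TOKEN,
    alphabet = model$alphabet,
    k = model$k,
    n_unique_das = model$counts$n_unique_das,
    monogram = as.list(model$counts$monogram),
    bigram = list(
      prev = rownames(big)[nz[, 1L]],
      nxt = colnames(big)[nz[, 2L]],
      count = as.integer(big[nz])
    ),
    trigram = as.list(model$counts$trigram)
  )
  jsonlite::write_json(obj, file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(file)
}

#' Read a model JSON artifact
#'
#' @param file Path written by [write_model_json()].
#' @param k Optional pseudocount override (`"default"` or a nonnegative
#'   number); by default the stored value is used.
#' @return A `first_order_model`.
#' @export
read_model_json <- function(file, k = NULL) {
  obj <- jsonlite::read_json(file, simplifyVector = TRUE)
  if (!identical(obj$format, "darchsim-model"))
    stop("not a darchsim model artifact: ", file)
  alphabet <- as.character(obj$alphabet)
  if (identical(obj$kind, "probabilities")) {
    ctx <- c(alphabet, .NULL_TOKEN)
    # rows and columns are serialised in context order (alphabet, then NULL)
    prob <- do.call(rbind, lapply(obj$prob, function(row)
      as.numeric(unlist(row))))
    dimnames(prob) <- list(prev = ctx, nxt = ctx)
    return(model_from_probabilities(prob, alphabet,
                                    k = if (is.null(k)) obj$k else k))
  }
  ctx <- c(alphabet, .NULL_TOKEN)
  nd <- length(alphabet)
  big <- matrix(0L, nd + 1L, nd + 1L, dimnames = list(prev = ctx, nxt = ctx))
  stored_null <- obj$null_token
  fix_null <- function(x) ifelse(x == stored_null, .NULL_TOKEN, x)
  big[cbind(match(fix_null(obj$bigram$prev), ctx),
            match(fix_null(obj$bigram$nxt), ctx))] <- as.integer(obj$bigram$count)
  mono <- setNames(integer(nd), alphabet)
  stored_mono <- unlist(obj$monogram)
  mono[names(stored_mono)] <- as.integer(stored_mono)
  trigram <- if (length(obj$trigram)) {
    tg <- unlist(obj$trigram)
    setNames(as.integer(tg), names(tg))
  } else setNames(integer(0), character(0))
  counts <- structure(
    list(monogram = mono, bigram = big, trigram = trigram,
         n_unique_das = as.integer(obj$n_unique_das), alphabet = alphabet),
    class = "count_tables"
  )
  build_model(counts, k = if (is.null(k)) obj$k else k)
}
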