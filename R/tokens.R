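# Sentinel marking DA termini. It is a context/continuation in the bigram
# model but never a member of an architecture or of the alphabet.
.NULL_TOKEN <- "<NULL>"

#' The NULL terminus sentinel
#'
#' Architectures are modelled with implicit NULL domains at the N- and
#' C-termini, so the bigram model has boundary pairs (NULL, first domain) and
#' (last domain, NULL). The sentinel is reserved: it may not appear inside an
#' architecture or in an alphabet.
#'
#' @return The sentinel string.
#' @export
null_token <- function() .NULL_TOKEN

# Validate a domain architecture: non-empty character vector, no NULL
# sentinel, optionally restricted to an alphabet.
assert_architecture <- function(da, alphabet = NULL) {
  if (!is.character(da) || length(da) < 1L)
    stop("a domain architecture must be a character vector of length >= 1")
  if (any(!nzchar(da)))
    stop("empty domain token")
  if (any(da == .NULL_TOKEN))
    stop("the NULL sentinel may not appear inside an architecture")
  if (!is.null(alphabet)) {
    bad <- setdiff(unique(da), alphabet)
    if (length(bad))
      stop("token(s) not in alphabet: ", paste(bad, collapse = ", "))
  }
  invisible(da)
}

assert_alphabet <- function(alphabet) {
  if (!is.character(alphabet) || length(alphabet) < 1L)
    stop("alphabet must be a non-empty character vector")
  if (anyDuplicated(alphabet))
    stop("alphabet contains duplicated tokens")
  if (any(!nzchar(alphabet)) || any(alphabet == .NULL_TOKEN))
    stop("alphabet tokens must be non-empty and distinct from the NULL sentinel")
  invisible(alphabet)
}
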