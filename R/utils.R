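`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1L && is.na(a))) b else a

svwStop <- function(class, msg, call. = FALSE) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = if (call.) sys.call(-1) else NULL)))
}

withSeed <- function(seed, code) withr::with_seed(as.integer(seed), code)

#' Serialise SAX words to strings
#'
#' Symbols are 0-based integers below the alphabet size. For alphabets up to
#' 26 the string uses letters (`a` = 0), the usual display form for SAX
#' words; larger alphabets fall back to dot-separated integers.
#'
#' @param symbols Integer vector of 0-based symbols.
#' @param alphabetSize Alphabet size the symbols were produced under.
#' @return `saxToString()` a single string; `stringToSax()` the integer
#'   vector.
#' @examples
#' saxToString(c(0, 11, 23), 24)
#' stringToSax("alx", 24)
#' @export
saxToString <- function(symbols, alphabetSize) {
  stopifnot(all(symbols >= 0), all(symbols < alphabetSize))
  if (alphabetSize <= 26L) paste(letters[symbols + 1L], collapse = "")
  else paste(symbols, collapse = ".")
}

#' @rdname saxToString
#' @param x String produced by `saxToString()`.
#' @export
stringToSax <- function(x, alphabetSize) {
  if (alphabetSize <= 26L) {
    sym <- match(strsplit(x, "")[[1]], letters) - 1L
    if (anyNA(sym)) stop("invalid SAX string")
  } else {
    sym <- as.integer(strsplit(x, ".", fixed = TRUE)[[1]])
  }
  if (any(sym >= alphabetSize)) stop("symbol outside alphabet")
  sym
}
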