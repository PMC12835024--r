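# Internal helpers shared across modules.

# Round half away from zero (base round() is banker's rounding).
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# MD5 of a UTF-8 string; goes through a tempfile because tools::md5sum
# only hashes files.
md5_string <- function(x) {
  tf <- tempfile(fileext = ".txt")
  on.exit(unlink(tf), add = TRUE)
  con <- file(tf, open = "wb")
  writeBin(charToRaw(enc2utf8(x)), con)
  close(con)
  unname(tools::md5sum(tf))
}

md5_file <- function(path) unname(tools::md5sum(path))

`%||%` <- function(a, b) if (is.null(a)) b else a

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

non_empty_string <- function(x) is_string(x) && nzchar(x)

# ---- dotted-path utilities -------------------------------------------------
# Paths address nested named lists; list entries use zero-based indices,
# e.g. "code.coding.0.system".

path_tokens <- function(path) {
  stopifnot(is_string(path), nzchar(path))
  strsplit(path, ".", fixed = TRUE)[[1]]
}

.tok_is_index <- function(tok) grepl("^[0-9]+$", tok)

path_exists <- function(tree, path) {
  toks <- path_tokens(path)
  node <- tree
  for (tok in toks) {
    if (.tok_is_index(tok)) {
      i <- as.integer(tok) + 1L
      if (!is.list(node) || length(node) < i) return(FALSE)
      node <- node[[i]]
    } else {
      if (!is.list(node) || is.null(names(node)) || !(tok %in% names(node))) return(FALSE)
      node <- node[[tok]]
    }
  }
  TRUE
}

path_get <- function(tree, path) {
  toks <- path_tokens(path)
  node <- tree
  for (tok in toks) {
    if (.tok_is_index(tok)) {
      i <- as.integer(tok) + 1L
      if (!is.list(node) || length(node) < i) return(NULL)
      node <- node[[i]]
    } else {
      if (!is.list(node) || is.null(names(node)) || !(tok %in% names(node))) return(NULL)
      node <- node[[tok]]
    }
  }
  node
}

.path_set_rec <- function(node, toks, value) {
  if (length(toks) == 0L) return(value)
  tok <- toks[[1L]]
  rest <- toks[-1L]
  if (.tok_is_index(tok)) {
    i <- as.integer(tok) + 1L
    if (is.null(node) || !is.list(node)) node <- list()
    while (length(node) < i - 1L) node[[length(node) + 1L]] <- list()
    sub <- if (i <= length(node)) node[[i]] else NULL
    node[[i]] <- .path_set_rec(sub, rest, value)
  } else {
    if (is.null(node) || !is.list(node)) node <- list()
    sub <- if (!is.null(names(node)) && tok %in% names(node)) node[[tok]] else NULL
    node[[tok]] <- .path_set_rec(sub, rest, value)
  }
  node
}

path_set <- function(tree, path, value) {
  .path_set_rec(tree, path_tokens(path), value)
}

path_drop <- function(tree, path) {
  if (!path_exists(tree, path)) return(tree)
  toks <- path_tokens(path)
  .drop_rec <- function(node, toks) {
    tok <- toks[[1L]]
    key <- if (.tok_is_index(tok)) as.integer(tok) + 1L else tok
    if (length(toks) == 1L) {
      node[[key]] <- NULL
      return(node)
    }
    node[[key]] <- .drop_rec(node[[key]], toks[-1L])
    node
  }
  .drop_rec(tree, toks)
}
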