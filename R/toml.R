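# Minimal TOML subset reader/writer.
#
# The installed R stack ships no TOML parser, so the input format is handled
# by a small hand-rolled implementation covering the subset the input files
# use: [tables], [[arrays of tables]], bare keys, basic strings, integers,
# floats, booleans, (nested) arrays, and inline tables.  Comments (#) and
# blank lines are allowed anywhere; multi-line arrays are supported.

strip_toml_comment <- function(line) {
  chars <- strsplit(line, "", fixed = TRUE)[[1]]
  in_str <- FALSE
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (in_str) {
      if (ch == "\\") i <- i + 1L else if (ch == "\"") in_str <- FALSE
    } else if (ch == "\"") {
      in_str <- TRUE
    } else if (ch == "#") {
      return(substr(line, 1L, i - 1L))
    }
    i <- i + 1L
  }
  line
}

toml_skip_ws <- function(s, pos) {
  n <- nchar(s)
  while (pos <= n && substr(s, pos, pos) %in% c(" ", "\t", "\n")) pos <- pos + 1L
  pos
}

toml_parse_string <- function(s, pos) {
  stopifnot(substr(s, pos, pos) == "\"")
  pos <- pos + 1L
  out <- character(0)
  n <- nchar(s)
  while (pos <= n) {
    ch <- substr(s, pos, pos)
    if (ch == "\\") {
      nxt <- substr(s, pos + 1L, pos + 1L)
      out <- c(out, switch(nxt,
        "n" = "\n", "t" = "\t", "\"" = "\"", "\\" = "\\",
        stop("unsupported escape \\", nxt, " in TOML string")
      ))
      pos <- pos + 2L
    } else if (ch == "\"") {
      return(list(value = paste0(out, collapse = ""), pos = pos + 1L))
    } else {
      out <- c(out, ch)
      pos <- pos + 1L
    }
  }
  stop("unterminated string in TOML input")
}

toml_parse_number <- function(s, pos) {
  m <- regmatches(
    substr(s, pos, nchar(s)),
    regexpr("^[+-]?(0x)?[0-9]*\\.?[0-9]+([eE][+-]?[0-9]+)?", substr(s, pos, nchar(s)))
  )
  if (length(m) == 0 || !nzchar(m)) stop("invalid TOML value at: ", substr(s, pos, pos + 20L))
  txt <- m[[1]]
  val <- if (grepl("[.eE]", txt) && !grepl("^0x", txt)) as.numeric(txt) else {
    v <- suppressWarnings(as.integer(txt))
    if (is.na(v)) as.numeric(txt) else v
  }
  list(value = val, pos = pos + nchar(txt))
}

toml_parse_value <- function(s, pos) {
  pos <- toml_skip_ws(s, pos)
  ch <- substr(s, pos, pos)
  if (ch == "\"") return(toml_parse_string(s, pos))
  if (ch == "[") return(toml_parse_array(s, pos))
  if (ch == "{") return(toml_parse_inline_table(s, pos))
  rest <- substr(s, pos, nchar(s))
  if (grepl("^true\\b", rest)) return(list(value = TRUE, pos = pos + 4L))
  if (grepl("^false\\b", rest)) return(list(value = FALSE, pos = pos + 5L))
  toml_parse_number(s, pos)
}

toml_parse_array <- function(s, pos) {
  stopifnot(substr(s, pos, pos) == "[")
  pos <- toml_skip_ws(s, pos + 1L)
  items <- list()
  repeat {
    if (substr(s, pos, pos) == "]") { pos <- pos + 1L; break }
    r <- toml_parse_value(s, pos)
    items[[length(items) + 1L]] <- r$value
    pos <- toml_skip_ws(s, r$pos)
    ch <- substr(s, pos, pos)
    if (ch == ",") pos <- toml_skip_ws(s, pos + 1L)
    else if (ch != "]") stop("malformed TOML array near: ", substr(s, pos, pos + 20L))
  }
  # homogeneous atomic arrays collapse to vectors; otherwise keep as list
  if (length(items) == 0L) return(list(value = character(0), pos = pos))
  atomic <- vapply(items, function(x) is.atomic(x) && length(x) == 1L, logical(1))
  value <- if (all(atomic)) {
    types <- vapply(items, function(x) class(x)[1], character(1))
    if (length(unique(types)) == 1L || all(types %in% c("integer", "numeric"))) {
      unlist(items)
    } else items
  } else items
  list(value = value, pos = pos)
}

toml_parse_inline_table <- function(s, pos) {
  stopifnot(substr(s, pos, pos) == "{")
  pos <- toml_skip_ws(s, pos + 1L)
  out <- list()
  repeat {
    if (substr(s, pos, pos) == "}") { pos <- pos + 1L; break }
    km <- regmatches(
      substr(s, pos, nchar(s)),
      regexpr("^(\"[^\"]*\"|[A-Za-z0-9_.-]+)", substr(s, pos, nchar(s)))
    )
    if (length(km) == 0) stop("malformed inline table near: ", substr(s, pos, pos + 20L))
    key <- gsub("^\"|\"$", "", km[[1]])
    pos <- toml_skip_ws(s, pos + nchar(km[[1]]))
    if (substr(s, pos, pos) != "=") stop("expected '=' in inline table")
    r <- toml_parse_value(s, pos + 1L)
    out[[key]] <- r$value
    pos <- toml_skip_ws(s, r$pos)
    ch <- substr(s, pos, pos)
    if (ch == ",") pos <- toml_skip_ws(s, pos + 1L)
    else if (ch != "}") stop("malformed inline table near: ", substr(s, pos, pos + 20L))
  }
  list(value = out, pos = pos)
}

#' Parse a TOML document (subset)
#'
#' Reads the TOML dialect used by the model/prior/experiment/config input
#' files.  Returns a nested named list; `[[array of tables]]` entries become
#' unnamed lists of named lists.
#'
#' @param path Path to a TOML file, or a length-one character string of TOML
#'   text when `text = TRUE`.
#' @param text Interpret `path` as literal TOML text instead of a file path.
#' @return A named list.
#' @keywords internal
parse_toml <- function(path, text = FALSE) {
  raw <- if (text) strsplit(path, "\n", fixed = TRUE)[[1]] else readLines(path, warn = FALSE)
  lines <- vapply(raw, strip_toml_comment, character(1), USE.NAMES = FALSE)
  root <- list()
  target_path <- character(0)   # path of the table assignments go into
  i <- 1L
  n <- length(lines)
  balanced <- function(s) {
    # bracket/brace balance outside strings, for multi-line values
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    depth <- 0L; in_str <- FALSE; j <- 1L
    while (j <= length(chars)) {
      ch <- chars[j]
      if (in_str) {
        if (ch == "\\") j <- j + 1L else if (ch == "\"") in_str <- FALSE
      } else if (ch == "\"") in_str <- TRUE
      else if (ch %in% c("[", "{")) depth <- depth + 1L
      else if (ch %in% c("]", "}")) depth <- depth - 1L
      j <- j + 1L
    }
    depth == 0L
  }
  get_path <- function(x, p) { for (k in p) x <- x[[k]]; x }
  set_path <- function(x, p, value) {
    if (length(p) == 0L) return(value)
    head <- p[[1]]
    sub <- if (is.character(head) && !is.null(x[[head]])) x[[head]] else
      if (!is.character(head) && length(x) >= head) x[[head]] else list()
    x[[head]] <- set_path(sub, p[-1L], value)
    x
  }
  while (i <= n) {
    line <- trimws(lines[[i]])
    if (!nzchar(line)) { i <- i + 1L; next }
    if (grepl("^\\[\\[", line)) {
      name <- trimws(gsub("^\\[\\[|\\]\\]$", "", line))
      keys <- strsplit(name, ".", fixed = TRUE)[[1]]
      arr <- tryCatch(get_path(root, as.list(keys)), error = function(e) NULL)
      if (is.null(arr)) arr <- list()
      arr[[length(arr) + 1L]] <- list()
      root <- set_path(root, as.list(keys), arr)
      target_path <- c(as.list(keys), list(length(arr)))
      i <- i + 1L
    } else if (grepl("^\\[", line)) {
      name <- trimws(gsub("^\\[|\\]$", "", line))
      keys <- as.list(strsplit(name, ".", fixed = TRUE)[[1]])
      existing <- tryCatch(get_path(root, keys), error = function(e) NULL)
      if (is.null(existing)) root <- set_path(root, keys, list())
      target_path <- keys
      i <- i + 1L
    } else {
      stmt <- line
      while (!balanced(stmt) && i < n) {
        i <- i + 1L
        stmt <- paste(stmt, trimws(lines[[i]]))
      }
      eq <- regexpr("=", stmt, fixed = TRUE)
      if (eq < 0) stop("malformed TOML line: ", line)
      key <- trimws(substr(stmt, 1L, eq - 1L))
      key <- gsub("^\"|\"$", "", key)
      r <- toml_parse_value(stmt, eq + 1L)
      tbl <- get_path(root, target_path)
      tbl[[key]] <- r$value
      root <- set_path(root, target_path, tbl)
      i <- i + 1L
    }
  }
  root
}

toml_fmt_scalar <- function(x) {
  if (is.character(x)) {
    paste0("\"", gsub("\"", "\\\\\"", gsub("\\\\", "\\\\\\\\", x)), "\"")
  } else if (is.logical(x)) {
    if (x) "true" else "false"
  } else if (is.integer(x)) {
    sprintf("%d", x)
  } else {
    s <- sprintf("%.17g", x)
    if (!grepl("[.eE]", s) && !grepl("inf|nan", s)) s <- paste0(s, ".0")
    s
  }
}

toml_fmt_value <- function(x) {
  if (is.atomic(x) && length(x) == 1L && is.null(names(x))) return(toml_fmt_scalar(x))
  if (is.atomic(x)) {
    return(paste0("[", paste(vapply(x, toml_fmt_scalar, character(1)), collapse = ", "), "]"))
  }
  if (is.list(x) && (is.null(names(x)) || !any(nzchar(names(x))))) {
    return(paste0("[", paste(vapply(x, toml_fmt_value, character(1)), collapse = ", "), "]"))
  }
  # named list -> inline table
  paste0("{", paste(
    vapply(seq_along(x), function(i) paste(names(x)[i], "=", toml_fmt_value(x[[i]])), character(1)),
    collapse = ", "
  ), "}")
}

is_record_array <- function(v) {
  is.list(v) && length(v) > 0L && is.null(names(v)) &&
    all(vapply(v, function(e) is.list(e) && !is.null(names(e)), logical(1)))
}

#' Serialize a named list to TOML (subset)
#'
#' Inverse of [parse_toml()] on the supported subset: top-level scalars and
#' arrays become `key = value` lines, named lists become `[tables]` (nested
#' named lists inside them are written as inline tables), and unnamed lists
#' of named lists become `[[arrays of tables]]`.
#'
#' @param x Named list.
#' @param path Output file path, or `NULL` to return the text.
#' @return The TOML text, invisibly when written to a file.
#' @keywords internal
write_toml <- function(x, path = NULL) {
  lines <- character(0)
  scalars <- names(x)[!vapply(x, function(v) is_record_array(v) ||
    (is.list(v) && !is.null(names(v))), logical(1))]
  for (key in scalars) lines <- c(lines, paste(key, "=", toml_fmt_value(x[[key]])))
  tables <- names(x)[vapply(x, function(v) is.list(v) && !is.null(names(v)), logical(1))]
  for (key in tables) {
    lines <- c(lines, "", paste0("[", key, "]"))
    tbl <- x[[key]]
    for (k in names(tbl)) lines <- c(lines, paste(k, "=", toml_fmt_value(tbl[[k]])))
  }
  arrays <- names(x)[vapply(x, is_record_array, logical(1))]
  for (key in arrays) {
    for (rec in x[[key]]) {
      lines <- c(lines, "", paste0("[[", key, "]]"))
      for (k in names(rec)) lines <- c(lines, paste(k, "=", toml_fmt_value(rec[[k]])))
    }
  }
  txt <- paste0(paste(lines, collapse = "\n"), "\n")
  if (is.null(path)) return(txt)
  writeLines(txt, path, sep = "")
  invisible(txt)
}
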