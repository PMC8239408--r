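# BEL 1.0 subset: terms, statements, documents.
#
# The grammar deliberately covers only the nine term functions and five
# relations used by literature-curated toxicology networks; anything else is
# an explicit "unsupported token" error rather than a silent skip.

# long (canonical) name per accepted function token
.bel_functions <- c(
  a = "abundance", abundance = "abundance",
  p = "protein", protein = "protein", proteinAbundance = "protein",
  r = "rna", rna = "rna", rnaAbundance = "rna",
  m = "microRNA", microRNA = "microRNA", microRNAAbundance = "microRNA",
  bp = "biologicalProcess", biologicalProcess = "biologicalProcess",
  path = "pathology", pathology = "pathology",
  complex = "complexAbundance", complexAbundance = "complexAbundance",
  act = "activity", activity = "activity",
  pmod = "proteinModification", proteinModification = "proteinModification"
)

# short token used by the canonical serialized form
.bel_short <- c(
  abundance = "a", protein = "p", rna = "r", microRNA = "m",
  biologicalProcess = "bp", pathology = "path",
  complexAbundance = "complex", activity = "act",
  proteinModification = "pmod"
)

.bel_relations <- c(
  "increases", "directlyIncreases", "decreases", "directlyDecreases",
  "association"
)

# symbolic relation tokens, longest first so "-|" is not eaten by "-"
.bel_rel_symbols <- c(
  "->" = "increases", "=>" = "directlyIncreases",
  "-|" = "decreases", "=|" = "directlyDecreases",
  "--" = "association"
)

.bel_molecular <- c("abundance", "protein", "rna", "microRNA",
                    "complexAbundance")

bel_parse_error <- function(msg, span) {
  stop(sprintf("BEL parse error: %s [at '%s']", msg, span), call. = FALSE)
}

# Typographic characters from papers and curation tools are normalized before
# tokenizing: curly quotes to straight quotes, unicode arrows/minus to ASCII.
normalize_bel_text <- function(x) {
  x <- gsub("“|”", '"', x)
  x <- gsub("‘|’", "'", x)
  x <- gsub("→", "->", x)
  x <- gsub("−", "-", x)
  x
}

#' Construct a BEL term
#'
#' @param fn canonical function name (one of the nine supported functions).
#' @param namespace controlled-vocabulary prefix (e.g. \code{"ZFIN"}), or
#'   \code{NA} for purely structural terms such as \code{act(...)}.
#' @param value entity name within the namespace, or \code{NA}.
#' @param inner list of nested \code{bel_term}s (e.g. the protein inside an
#'   activity, a \code{pmod} inside a protein).
#' @param args character vector of bare arguments (used by \code{pmod}).
#' @return an object of class \code{bel_term} with a \code{canonical_id}.
#' @keywords internal
new_bel_term <- function(fn, namespace = NA_character_, value = NA_character_,
                         inner = list(), args = character()) {
  term <- structure(
    list(fn = fn, namespace = namespace, value = value,
         inner = inner, args = args, canonical_id = NA_character_),
    class = "bel_term"
  )
  term$canonical_id <- serialize_term(term)
  term
}

# index of the closing paren matching the open paren at `open`, quote-aware
.match_paren <- function(chars, open) {
  depth <- 0L
  in_quote <- FALSE
  for (k in open:length(chars)) {
    ch <- chars[k]
    if (in_quote) {
      if (ch == '"') in_quote <- FALSE
      next
    }
    if (ch == '"') in_quote <- TRUE
    else if (ch == "(") depth <- depth + 1L
    else if (ch == ")") {
      depth <- depth - 1L
      if (depth == 0L) return(k)
    }
  }
  NA_integer_
}

# split on top-level commas, outside quotes and parentheses
.split_top_level <- function(s) {
  if (!nzchar(trimws(s))) return(character())
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  depth <- 0L
  in_quote <- FALSE
  parts <- character()
  buf <- character()
  for (ch in chars) {
    if (in_quote) {
      buf <- c(buf, ch)
      if (ch == '"') in_quote <- FALSE
      next
    }
    if (ch == '"') { in_quote <- TRUE; buf <- c(buf, ch); next }
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") depth <- depth - 1L
    if (ch == "," && depth == 0L) {
      parts <- c(parts, paste(buf, collapse = ""))
      buf <- character()
    } else buf <- c(buf, ch)
  }
  c(parts, paste(buf, collapse = ""))
}

.unquote <- function(x) {
  x <- trimws(x)
  if (nchar(x) >= 2 && startsWith(x, '"') && endsWith(x, '"')) {
    substr(x, 2L, nchar(x) - 1L)
  } else x
}

.parse_term_str <- function(s) {
  s <- trimws(s)
  m <- regmatches(s, regexec("^([A-Za-z]+)\\s*\\(", s))[[1]]
  if (length(m) == 0) {
    if (grepl("\\)", s) && !grepl("\\(", s))
      bel_parse_error("unbalanced parentheses", s)
    bel_parse_error("expected a function token followed by '('", s)
  }
  tok <- m[2]
  if (!tok %in% names(.bel_functions))
    bel_parse_error(sprintf("unsupported function token '%s'", tok), s)
  fn <- .bel_functions[[tok]]

  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  open <- regexpr("\\(", s)[1]
  close <- .match_paren(chars, open)
  if (is.na(close)) bel_parse_error("unbalanced parentheses", s)
  if (nzchar(trimws(substr(s, close + 1L, nchar(s)))))
    bel_parse_error("unexpected text after closing parenthesis", s)
  body <- substr(s, open + 1L, close - 1L)

  namespace <- NA_character_
  value <- NA_character_
  inner <- list()
  args <- character()
  for (part in .split_top_level(body)) {
    p <- trimws(part)
    if (grepl("^[A-Za-z]+\\s*\\(", p)) {
      inner <- c(inner, list(.parse_term_str(p)))
    } else if (grepl(":", sub('"[^"]*"', "", p))) {
      colon <- regexpr(":", p, fixed = TRUE)[1]
      ns <- trimws(substr(p, 1L, colon - 1L))
      val <- .unquote(substr(p, colon + 1L, nchar(p)))
      if (!nzchar(ns) || !nzchar(val))
        bel_parse_error("empty namespace or value", p)
      if (!is.na(namespace))
        bel_parse_error("more than one namespace:value argument", p)
      namespace <- ns
      value <- val
    } else {
      if (!nzchar(p)) bel_parse_error("empty argument", s)
      args <- c(args, .unquote(p))
    }
  }
  new_bel_term(fn, namespace, value, inner, args)
}

.validate_term <- function(term, parent_fn, span) {
  fn <- term$fn
  if (fn == "activity") {
    mol <- term$inner
    if (length(mol) != 1L || !is.na(term$namespace) || length(term$args))
      bel_parse_error("activity terms wrap exactly one molecular term", span)
    if (!mol[[1]]$fn %in% .bel_molecular)
      bel_parse_error("activity may only wrap a molecular term", span)
  } else if (fn == "proteinModification") {
    if (!identical(parent_fn, "protein"))
      bel_parse_error("pmod occurs only inside protein terms", span)
    if (length(term$args) < 1L || !is.na(term$namespace))
      bel_parse_error("pmod takes one or more plain arguments", span)
  } else if (fn == "complexAbundance") {
    if (is.na(term$namespace) && length(term$inner) == 0L)
      bel_parse_error("complex requires a namespace:value or member terms",
                      span)
  } else {
    if (is.na(term$namespace) || is.na(term$value))
      bel_parse_error(sprintf("empty namespace or value in %s(...)", fn), span)
    if (fn != "protein" && length(term$inner))
      bel_parse_error(sprintf("%s does not take nested terms", fn), span)
    if (fn == "protein" &&
        !all(vapply(term$inner, function(t) t$fn, "") ==
             "proteinModification"))
      bel_parse_error("protein may only nest pmod terms", span)
  }
  for (sub in term$inner) .validate_term(sub, parent_fn = fn, span = span)
  invisible(term)
}

#' Parse a single BEL term
#'
#' Parses one term of the supported BEL 1.0 subset, e.g.
#' \code{act(p(ZFIN:gbx2))} or \code{bp(GOBP:"cell proliferation")}.
#' Whitespace outside quoted strings is ignored; quoted values are preserved
#' verbatim (including case); typographic quotes are normalized to straight
#' quotes.
#'
#' @param text a single term with balanced parentheses.
#' @return a \code{bel_term}: list with fields \code{fn}, \code{namespace},
#'   \code{value}, \code{inner} (nested terms), \code{args}, and
#'   \code{canonical_id} (the canonical serialized form).
#' @examples
#' parse_term('bp(GOBP:"cell proliferation")')$canonical_id
#' @export
parse_term <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  s <- normalize_bel_text(text)
  term <- .parse_term_str(s)
  .validate_term(term, parent_fn = NULL, span = trimws(s))
  term
}

#' Serialize a BEL term to its canonical form
#'
#' Uses short function tokens (\code{a}, \code{p}, \code{r}, \code{m},
#' \code{bp}, \code{path}, \code{complex}, \code{act}, \code{pmod}) and
#' minimal quoting (values containing spaces, hyphens, commas, colons or
#' parentheses are quoted). \code{parse_term} inverts it.
#'
#' @param term a \code{bel_term}.
#' @return single string.
#' @export
serialize_term <- function(term) {
  stopifnot(inherits(term, "bel_term"))
  parts <- character()
  if (!is.na(term$namespace)) {
    val <- term$value
    if (grepl("[ ,():\"-]", val)) val <- paste0('"', val, '"')
    parts <- c(parts, paste0(term$namespace, ":", val))
  }
  parts <- c(parts, vapply(term$inner, serialize_term, ""), term$args)
  paste0(.bel_short[[term$fn]], "(", paste(parts, collapse = ","), ")")
}

#' @export
print.bel_term <- function(x, ...) {
  cat("<bel_term> ", x$canonical_id, "\n", sep = "")
  invisible(x)
}

#' @export
format.bel_term <- function(x, ...) x$canonical_id

# ---- statements -------------------------------------------------------------

#' Construct a BEL statement
#'
#' @param subject,object \code{bel_term}s.
#' @param relation one of \code{increases}, \code{directlyIncreases},
#'   \code{decreases}, \code{directlyDecreases}, \code{association}.
#' @param annotations named list (possibly empty); values may be character
#'   vectors (multi-valued annotations).
#' @param citation list (possibly empty), typically with elements
#'   \code{type}, \code{name}, \code{id} and optionally \code{evidence}.
#' @return object of class \code{bel_statement}.
#' @export
new_bel_statement <- function(subject, relation, object,
                              annotations = list(), citation = list()) {
  stopifnot(inherits(subject, "bel_term"), inherits(object, "bel_term"))
  if (!relation %in% .bel_relations)
    stop("unknown relation: ", relation, call. = FALSE)
  structure(
    list(subject = subject, relation = relation, object = object,
         annotations = annotations, citation = citation),
    class = "bel_statement"
  )
}

# locate relation tokens at top level; returns data.frame(start, end, relation)
.find_relations <- function(s) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(chars)
  depth <- 0L
  in_quote <- FALSE
  hits <- list()
  k <- 1L
  while (k <= n) {
    ch <- chars[k]
    if (in_quote) {
      if (ch == '"') in_quote <- FALSE
      k <- k + 1L
      next
    }
    if (ch == '"') { in_quote <- TRUE; k <- k + 1L; next }
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") depth <- depth - 1L
    if (depth == 0L) {
      rest <- substr(s, k, n)
      matched <- FALSE
      for (sym in names(.bel_rel_symbols)) {
        if (startsWith(rest, sym)) {
          hits <- c(hits, list(list(start = k, end = k + nchar(sym) - 1L,
                                    relation = .bel_rel_symbols[[sym]])))
          k <- k + nchar(sym)
          matched <- TRUE
          break
        }
      }
      if (matched) next
      w <- regmatches(rest, regexpr("^[A-Za-z]+", rest))
      if (length(w) && w %in% .bel_relations &&
          (k == 1L || grepl("\\s", chars[k - 1L]))) {
        after <- k + nchar(w)
        if (after > n || grepl("\\s", chars[after])) {
          hits <- c(hits, list(list(start = k, end = after - 1L,
                                    relation = w)))
          k <- after
          next
        }
      }
    }
    k <- k + 1L
  }
  do.call(rbind, lapply(hits, as.data.frame))
}

#' Parse one BEL statement line
#'
#' Accepts relations in word form (\code{increases}, \code{decreases},
#' \code{directlyIncreases}, \code{directlyDecreases}, \code{association})
#' and symbolic form (\code{->}, \code{-|}, \code{=>}, \code{=|}, \code{--});
#' the typographic arrow \dQuote{\eqn{\rightarrow}} and minus-bar are
#' normalized before tokenizing.
#'
#' @param line a single statement line.
#' @param annotations,citation carried onto the returned statement (used by
#'   \code{\link{parse_document}}).
#' @return a \code{bel_statement}.
#' @examples
#' parse_statement("a(CHEBI:ethanol) -> path(MESHD:Microcephaly)")$relation
#' @export
parse_statement <- function(line, annotations = list(), citation = list()) {
  stopifnot(is.character(line), length(line) == 1L)
  s <- trimws(normalize_bel_text(line))
  rel <- .find_relations(s)
  if (is.null(rel) || nrow(rel) == 0L)
    bel_parse_error("missing or unknown relation token", s)
  if (nrow(rel) > 1L)
    bel_parse_error("more than one relation on a line", s)
  subject <- parse_term(substr(s, 1L, rel$start - 1L))
  object <- parse_term(substr(s, rel$end + 1L, nchar(s)))
  new_bel_statement(subject, rel$relation, object, annotations, citation)
}

#' Serialize a statement to canonical single-line form
#'
#' Canonical form uses word-form relations; \code{parse_statement} inverts it.
#'
#' @param stmt a \code{bel_statement}.
#' @return single string.
#' @export
serialize_statement <- function(stmt) {
  stopifnot(inherits(stmt, "bel_statement"))
  paste(serialize_term(stmt$subject), stmt$relation,
        serialize_term(stmt$object))
}

#' @export
print.bel_statement <- function(x, ...) {
  cat("<bel_statement> ", serialize_statement(x), "\n", sep = "")
  if (length(x$annotations))
    cat("  annotations: ", paste(names(x$annotations), collapse = ", "),
        "\n", sep = "")
  invisible(x)
}

# ---- documents --------------------------------------------------------------

# parse the value of a SET line: "v" or {"a","b",...}
.parse_set_value <- function(v) {
  v <- trimws(v)
  if (startsWith(v, "{") && endsWith(v, "}")) {
    inner <- substr(v, 2L, nchar(v) - 1L)
    vapply(.split_top_level(inner), .unquote, "", USE.NAMES = FALSE)
  } else {
    .unquote(v)
  }
}

#' Parse an OpenBEL-style script into statements
#'
#' Tolerates \code{DEFINE NAMESPACE}/\code{DEFINE ANNOTATION} lines,
#' \code{SET}/\code{UNSET} annotation lines (including \code{SET Citation}
#' and \code{SET Evidence}), \code{#} comments and blank lines. Each returned
#' statement carries the annotation state active at its line and the most
#' recent citation; statements appear in file order.
#'
#' @param lines character vector of document lines.
#' @return list of \code{bel_statement}; attribute \code{"namespaces"} lists
#'   DEFINE'd namespace keywords.
#' @export
parse_document <- function(lines) {
  stopifnot(is.character(lines))
  annotations <- list()
  citation <- list()
  namespaces <- character()
  statements <- list()
  for (i in seq_along(lines)) {
    raw <- normalize_bel_text(lines[i])
    ln <- trimws(raw)
    if (!nzchar(ln) || startsWith(ln, "#")) next
    if (grepl("^DEFINE\\s", ln)) {
      m <- regmatches(ln, regexec("^DEFINE\\s+NAMESPACE\\s+(\\S+)", ln))[[1]]
      if (length(m)) namespaces <- c(namespaces, m[2])
      next
    }
    if (grepl("^UNSET\\s", ln)) {
      key <- trimws(sub("^UNSET\\s+", "", ln))
      if (identical(key, "ALL")) {
        annotations <- list()
        citation <- list()
      } else if (identical(key, "Citation")) {
        citation <- list()
      } else if (key %in% names(annotations)) {
        annotations[[key]] <- NULL
      } else {
        warning(sprintf("line %d: UNSET of annotation '%s' never set",
                        i, key), call. = FALSE)
      }
      next
    }
    if (grepl("^SET\\s", ln)) {
      m <- regmatches(ln, regexec("^SET\\s+(\\S+)\\s*=\\s*(.+)$", ln))[[1]]
      if (length(m) == 0)
        stop(sprintf("line %d: malformed SET line: %s", i, ln), call. = FALSE)
      key <- m[2]
      val <- .parse_set_value(m[3])
      if (identical(key, "Citation")) {
        citation <- list(
          type = if (length(val) >= 1) val[[1]] else NA_character_,
          name = if (length(val) >= 2) val[[2]] else NA_character_,
          id = if (length(val) >= 3) val[[3]] else NA_character_
        )
      } else if (identical(key, "Evidence")) {
        citation$evidence <- paste(val, collapse = " ")
      } else {
        annotations[[key]] <- val
      }
      next
    }
    stmt <- tryCatch(
      parse_statement(ln, annotations = annotations, citation = citation),
      error = function(e)
        stop(sprintf("line %d: %s", i, conditionMessage(e)), call. = FALSE)
    )
    statements <- c(statements, list(stmt))
  }
  attr(statements, "namespaces") <- namespaces
  statements
}

#' Read a BEL script file
#'
#' @param path path to a UTF-8 BEL script, one statement per line.
#' @return see \code{\link{parse_document}}.
#' @export
read_bel <- function(path) {
  parse_document(readLines(path, encoding = "UTF-8", warn = FALSE))
}

#' Write statements as JSON lines
#'
#' One JSON object per line with the canonical subject/object strings, the
#' relation, annotations and citation — a stable hand-off format for
#' downstream tooling.
#'
#' @param statements list of \code{bel_statement}.
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_statements_jsonl <- function(statements, path) {
  lines <- vapply(statements, function(s) {
    jsonlite::toJSON(list(
      subject = s$subject$canonical_id,
      relation = s$relation,
      object = s$object$canonical_id,
      annotations = s$annotations,
      citation = s$citation
    ), auto_unbox = TRUE)
  }, "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
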