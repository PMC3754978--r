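# Readers for the three plain-text inputs: pair tables, FASTA sequences and
# per-drug fingerprint tables. Pair and fingerprint tables use a minimal
# whitespace-delimited dialect: '#' starts a comment, blank lines are ignored,
# and an optional header line naming the id columns is recognised and skipped.

# split a file into non-blank, non-comment lines, keeping original line numbers
delim_lines <- function(path) {
  raw <- readLines(path, warn = FALSE)
  raw <- sub("#.*$", "", raw)
  keep <- grepl("\\S", raw)
  list(text = raw[keep], lineno = which(keep))
}

is_header_line <- function(tokens) {
  any(grepl("^(gpcr|drug|protein|target|label|id)", tolower(tokens)))
}

#' Read a GPCR-drug pair table
#'
#' Reads a whitespace- or tab-delimited table of GPCR-drug pairs. Each line
#' carries a GPCR identifier (e.g. `hsa:10161`), a drug identifier
#' (e.g. `D00528`) and, optionally, a 0/1 interaction label
#' (1 = interactive, 0 = non-interactive). `#` comments and an optional
#' header line are ignored.
#'
#' @param path Path to the table.
#' @param label `"from-column"` (default) to take labels from the third
#'   column, or `"interactive"` / `"non-interactive"` to assign one label to
#'   every pair in the file (for files listing only one subset).
#' @return A tibble with columns `gpcr_id`, `drug_id` and `label`
#'   (`"interactive"` or `"non-interactive"`), one row per pair, in file
#'   order.
#' @export
read_pair_table <- function(path, label = c("from-column", "interactive",
                                            "non-interactive")) {
  label <- match.arg(label)
  ln <- delim_lines(path)
  rows <- lapply(seq_along(ln$text), function(i) {
    tok <- strsplit(trimws(ln$text[i]), "\\s+")[[1]]
    if (i == 1 && is_header_line(tok)) return(NULL)
    need <- if (label == "from-column") 3L else 2L
    if (length(tok) < need) {
      abort(sprintf("malformed pair line %d: expected %d fields, found %d",
                    ln$lineno[i], need, length(tok)))
    }
    lab <- switch(label,
      "from-column" = {
        if (!tok[3] %in% c("0", "1")) {
          abort(sprintf("malformed pair line %d: label must be 0 or 1, got '%s'",
                        ln$lineno[i], tok[3]))
        }
        if (tok[3] == "1") "interactive" else "non-interactive"
      },
      label)
    tibble(gpcr_id = tok[1], drug_id = tok[2], label = lab)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble(gpcr_id = character(), drug_id = character(),
                  label = character()))
  }
  key <- paste(out$gpcr_id, out$drug_id)
  if (anyDuplicated(key)) {
    abort(sprintf("duplicate pair(s): %s",
                  paste(unique(key[duplicated(key)]), collapse = ", ")))
  }
  out
}

#' Read protein sequences from a FASTA file
#'
#' Identifiers are the first whitespace-delimited token after `>`; sequences
#' are uppercased with line breaks removed. Characters outside the 20
#' standard residue letters are kept but reported with a warning, so that
#' downstream featurisation can decide how to treat them.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `gpcr_id` and `sequence`.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate FASTA identifier(s): %s",
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  seqs <- toupper(as.character(set))
  odd <- vapply(seqs, function(s) {
    any(!strsplit(s, "")[[1]] %in% AA_ALPHABET)
  }, logical(1))
  if (any(odd)) {
    warn(sprintf("sequence(s) with non-standard residue letters: %s",
                 paste(ids[odd], collapse = ", ")))
  }
  tibble(gpcr_id = ids, sequence = unname(seqs))
}

#' Read a per-drug fingerprint table
#'
#' Each line holds a drug identifier followed by either a single
#' 256-character hexadecimal string or 256 whitespace-separated integers in
#' \[0, 15\] — the digit form of a path-based 2D molecular fingerprint.
#'
#' @param path Path to the table.
#' @return A tibble with columns `drug_id` and `digits` (a list column of
#'   integer vectors, each of length 256).
#' @export
read_fingerprint_table <- function(path) {
  ln <- delim_lines(path)
  rows <- lapply(seq_along(ln$text), function(i) {
    tok <- strsplit(trimws(ln$text[i]), "\\s+")[[1]]
    if (i == 1 && is_header_line(tok)) return(NULL)
    id <- tok[1]
    body <- tok[-1]
    digits <- if (length(body) == 1L) {
      parse_fingerprint_hex(id, body)$digits[[1]]
    } else {
      d <- suppressWarnings(as.integer(body))
      if (anyNA(d)) {
        abort(sprintf("fingerprint for '%s': non-integer digit field", id))
      }
      d
    }
    if (length(digits) != 256L) {
      abort(sprintf("fingerprint for '%s': expected 256 digits, found %d",
                    id, length(digits)))
    }
    if (any(digits < 0L | digits > 15L)) {
      abort(sprintf("fingerprint for '%s': digit outside [0, 15]", id))
    }
    tibble(drug_id = id, digits = list(digits))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble(drug_id = character(), digits = list()))
  }
  if (anyDuplicated(out$drug_id)) {
    abort(sprintf("duplicate drug identifier(s): %s",
                  paste(unique(out$drug_id[duplicated(out$drug_id)]),
                        collapse = ", ")))
  }
  out
}

#' Write a delimited table with a versioned parameter header
#'
#' Writes a tibble as tab-separated text preceded by `#` comment lines
#' recording the package version and the parameter set that produced the
#' table, so every artifact is regenerable from its own header.
#'
#' @param df Data frame to write.
#' @param path Output path.
#' @param params Named list of parameters to record in the header.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(df, path, params = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# gdip %s", gdip_version()), con)
  if (length(params)) {
    writeLines(sprintf("# %s=%s", names(params),
                       vapply(params, function(x) paste(format(x, digits = 17),
                                                        collapse = ","),
                              character(1))), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
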