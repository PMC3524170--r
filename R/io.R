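## Readers and writers for the formats the pipeline touches: FASTA sequences,
## delimiter-separated tables with a header row (TSV by default, comma
## auto-detected, '#' comment lines skipped), and a read-only subset of the
## NMR-STAR v3 assigned-chemical-shift loop.

TABLE_SCHEMAS <- list(
  decay        = c("residue_number", "residue_type", "delay_ms", "intensity"),
  noe          = c("residue_number", "residue_type", "intensity_sat",
                   "intensity_eq", "noise_rms_sat", "noise_rms_eq"),
  shifts       = c("residue_number", "residue_type"),
  denaturation = c("denaturant_M", "signal"),
  tempseries   = c("residue_number", "residue_type", "temperature", "hn_shift_ppm"),
  coupling     = c("residue_number", "residue_type", "j_hz"),
  peaks        = c("residue_number", "residue_type")
)

#' Read a protein sequence from FASTA
#'
#' Reads the first record of a FASTA file; lowercase letters are accepted and
#' case-folded.
#'
#' @param path FASTA file path.
#' @return a [sequence_record()].
#' @export
read_sequence <- function(path) {
  set <- tryCatch(Biostrings::readAAStringSet(path),
                  error = function(e) stop("cannot parse FASTA '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  if (length(set) == 0) stop("no FASTA record in '", path, "'", call. = FALSE)
  residues <- strsplit(toupper(as.character(set[[1]])), "")[[1]]
  bad <- which(!(residues %in% AA1))
  if (length(bad))
    stop("non-amino-acid character '", residues[bad[1]], "' at position ",
         bad[1], " in '", path, "'", call. = FALSE)
  sequence_record(residues, id = names(set)[1], numbering_offset = 1L)
}

detect_sep <- function(path) {
  lines <- readLines(path, n = 25L, warn = FALSE)
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) == 0) stop("empty table file '", path, "'", call. = FALSE)
  if (sum(grepl("\t", lines)) >= sum(grepl(",", lines))) "\t" else ","
}

#' Read a typed pipeline table
#'
#' Reads a delimiter-separated file with a header row and validates it against
#' one of the pipeline schemas, returning the corresponding typed table.
#' Tab-separated by default; comma separation is auto-detected. Lines starting
#' with `#` (provenance headers) are skipped. Missing optional cells stay `NA`.
#'
#' @param path file path.
#' @param schema one of "decay", "noe", "shifts", "denaturation", "tempseries",
#'   "coupling", "peaks".
#' @param ... passed to the table constructor (e.g. `experiment` for decay
#'   tables, `condition_label` for shift tables, `unit` for temperature
#'   series).
#' @param absent_residues residue numbers that should not appear (e.g.
#'   unobservable N-terminal residues); their presence triggers a warning,
#'   not an error.
#' @return the typed table for the schema.
#' @export
read_table <- function(path, schema, ..., absent_residues = NULL) {
  schema <- match.arg(schema, names(TABLE_SCHEMAS))
  sep <- detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE)
  required <- TABLE_SCHEMAS[[schema]]
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("'", path, "': missing required column(s) ",
         paste(missing_cols, collapse = ","), call. = FALSE)
  numeric_cols <- setdiff(names(df), "residue_type")
  for (col in numeric_cols) {
    if (!is.numeric(df[[col]])) {
      suppressWarnings(converted <- as.numeric(df[[col]]))
      bad <- which(!is.na(df[[col]]) & df[[col]] != "" & is.na(converted))
      if (length(bad))
        stop("'", path, "': non-numeric value '", df[[col]][bad[1]],
             "' in numeric column ", col, call. = FALSE)
      df[[col]] <- converted
    }
  }
  if (!is.null(absent_residues) && "residue_number" %in% names(df)) {
    hit <- intersect(df$residue_number, absent_residues)
    if (length(hit))
      warning("table contains residue(s) expected to be absent: ",
              paste(hit, collapse = ","), call. = FALSE)
  }
  if (schema %in% c("noe", "shifts", "coupling", "peaks") &&
      anyDuplicated(df$residue_number))
    stop("'", path, "': duplicate residue_number", call. = FALSE)
  switch(schema,
    decay        = decay_table(df, ...),
    noe          = noe_table(df),
    shifts       = shift_table(df, ...),
    denaturation = denaturation_table(df$denaturant_M, df$signal, ...),
    tempseries   = temperature_table(df, ...),
    coupling     = coupling_table(df),
    peaks        = peak_table(df))
}

#' Write a pipeline table as TSV
#'
#' Writes any pipeline table (or plain data.frame) as TSV with a `#`-prefixed
#' provenance header (package version and content hash). [read_table()] skips
#' the header, so `read_table(write_table(x))` round-trips.
#'
#' @param x data.frame to write.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  df <- as.data.frame(x)
  tmp <- tempfile(); on.exit(unlink(tmp))
  utils::write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  hash <- unname(tools::md5sum(tmp))
  ver <- as.character(utils::packageVersion("unfoldnmr"))
  con <- file(path, "w"); on.exit(close(con), add = TRUE)
  writeLines(sprintf("# unfoldnmr %s | md5 %s", ver, hash), con)
  writeLines(readLines(tmp), con)
  invisible(path)
}

#' Read chemical shifts from an NMR-STAR v3 file
#'
#' Minimal reader for the assigned-chemical-shift loop of an NMR-STAR v3 file
#' (the format of BMRB depositions): finds the `loop_` whose tags belong to
#' `_Atom_chem_shift`, and keeps atoms H, N, CA, CB and HA (H is stored as
#' `hn`). Atoms outside that set are ignored. If the same (residue, atom) pair
#' occurs twice, the last occurrence wins with a warning. An empty loop yields
#' an empty table, not an error.
#'
#' @param path NMR-STAR file path.
#' @param condition_label condition label for the returned table.
#' @return a [shift_table()].
#' @export
read_nmrstar_shifts <- function(path, condition_label = "") {
  lines <- trimws(readLines(path, warn = FALSE))
  loop_starts <- which(lines == "loop_")
  if (length(loop_starts) == 0)
    stop("'", path, "': no loop_ found (not NMR-STAR?)", call. = FALSE)
  for (start in loop_starts) {
    i <- start + 1L
    tags <- character()
    while (i <= length(lines) && startsWith(lines[i], "_")) {
      tags <- c(tags, lines[i]); i <- i + 1L
    }
    if (!any(grepl("^_Atom_chem_shift\\.", tags))) next
    rows <- list()
    while (i <= length(lines) && lines[i] != "stop_") {
      if (nzchar(lines[i]) && !startsWith(lines[i], "#"))
        rows[[length(rows) + 1L]] <- strsplit(lines[i], "[[:space:]]+")[[1]]
      i <- i + 1L
    }
    return(parse_shift_loop(tags, rows, condition_label, path))
  }
  stop("'", path, "': no _Atom_chem_shift loop found", call. = FALSE)
}

parse_shift_loop <- function(tags, rows, condition_label, path) {
  col <- function(tag) match(paste0("_Atom_chem_shift.", tag), tags)
  needed <- c(seq_col = col("Comp_index_ID"), type_col = col("Comp_ID"),
              atom_col = col("Atom_ID"), val_col = col("Val"))
  if (any(is.na(needed)))
    stop("'", path, "': shift loop lacks Comp_index_ID/Comp_ID/Atom_ID/Val tags",
         call. = FALSE)
  empty <- data.frame(residue_number = integer(), residue_type = character(),
                      hn = numeric(), n = numeric(), ca = numeric(),
                      cb = numeric(), ha = numeric(), stringsAsFactors = FALSE)
  if (length(rows) == 0) return(shift_table(empty, condition_label))
  keep_atoms <- c(H = "hn", N = "n", CA = "ca", CB = "cb", HA = "ha")
  recs <- list()  # keyed residue|atom, last wins
  dup_seen <- FALSE
  for (r in rows) {
    atom <- toupper(r[needed["atom_col"]])
    if (!(atom %in% names(keep_atoms))) next
    key <- paste0(r[needed["seq_col"]], "|", atom)
    if (!is.null(recs[[key]])) dup_seen <- TRUE
    recs[[key]] <- list(num = as.integer(r[needed["seq_col"]]),
                        type = aa_three_to_one(r[needed["type_col"]]),
                        atom = keep_atoms[[atom]],
                        val = as.numeric(r[needed["val_col"]]))
  }
  if (dup_seen)
    warning("'", path, "': duplicate atom entries in shift loop; last occurrence wins",
            call. = FALSE)
  if (length(recs) == 0) return(shift_table(empty, condition_label))
  nums <- sort(unique(vapply(recs, `[[`, 1L, "num")))
  df <- data.frame(residue_number = nums, residue_type = NA_character_,
                   hn = NA_real_, n = NA_real_, ca = NA_real_,
                   cb = NA_real_, ha = NA_real_, stringsAsFactors = FALSE)
  for (rec in recs) {
    i <- match(rec$num, df$residue_number)
    df$residue_type[i] <- rec$type
    df[[rec$atom]][i] <- rec$val
  }
  shift_table(df, condition_label)
}
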