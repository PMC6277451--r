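# On-disk formats: mzML (read/write, minimal HUPO-PSI subset), NIST MSP
# spectrum libraries, the package's SQLite library format, FASTA digestion.

b64_doubles_enc <- function(x) {
  jsonlite::base64_enc(writeBin(as.numeric(x), raw(), size = 8L,
                                endian = "little"))
}

b64_doubles_dec <- function(txt, n) {
  if (is.na(txt) || !nzchar(txt)) return(numeric(0))
  readBin(jsonlite::base64_dec(txt), "double", n = n, size = 8L,
          endian = "little")
}

#' Read a centroided DIA run from mzML
#'
#' Supports the subset of mzML this package writes and that common
#' converters emit for centroided data: 64-bit (or 32-bit) uncompressed
#' binary arrays, scan start time in minutes or seconds, and isolation
#' window target/offsets on MS2 scans.
#'
#' @param path mzML file path
#' @param demultiplex if TRUE, 50%-overlapped MS2 spectra are replaced by
#'   demultiplexed half-width pseudo-spectra (see
#'   \code{\link{demultiplex_run}})
#' @param tol_ppm fragment-matching tolerance used during demultiplexing
#' @return a \code{DIARun}
#' @export
read_mzml <- function(path, demultiplex = FALSE, tol_ppm = 10) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  run_node <- xml2::xml_find_first(doc, ".//run")
  run_id <- xml2::xml_attr(run_node, "id")
  if (is.na(run_id)) run_id <- tools::file_path_sans_ext(basename(path))
  nodes <- xml2::xml_find_all(doc, ".//spectrumList/spectrum")
  spectra <- vector("list", length(nodes))
  for (k in seq_along(nodes)) {
    nd <- nodes[[k]]
    scan_id <- xml2::xml_attr(nd, "id")
    cv <- function(node, acc)
      xml2::xml_attr(xml2::xml_find_first(
        node, sprintf(".//cvParam[@accession='%s']", acc)), "value")
    has <- function(node, acc)
      !is.na(xml2::xml_find_first(
        node, sprintf(".//cvParam[@accession='%s']", acc)))
    if (has(nd, "MS:1000128"))
      stop("profile-mode spectrum ", scan_id, ": centroided data required")
    ms_level <- as.integer(cv(nd, "MS:1000511"))
    rt_node <- xml2::xml_find_first(nd, ".//scan/cvParam[@accession='MS:1000016']")
    rt <- as.numeric(xml2::xml_attr(rt_node, "value"))
    unit <- xml2::xml_attr(rt_node, "unitName")
    if (!is.na(unit) && unit == "second") rt <- rt / 60

    iso_c <- NA_real_; iso_w <- NA_real_
    if (ms_level == 2L) {
      iw <- xml2::xml_find_first(nd, ".//precursor/isolationWindow")
      if (is.na(iw))
        stop("MS2 spectrum ", scan_id, " lacks an isolation window")
      tgt <- as.numeric(cv(iw, "MS:1000827"))
      lo <- as.numeric(cv(iw, "MS:1000828"))
      hi <- as.numeric(cv(iw, "MS:1000829"))
      if (is.na(tgt) || is.na(lo) || is.na(hi))
        stop("MS2 spectrum ", scan_id, " lacks isolation width metadata")
      iso_c <- tgt + (hi - lo) / 2
      iso_w <- lo + hi
    }

    arrays <- xml2::xml_find_all(nd, ".//binaryDataArray")
    mzs <- numeric(0); ints <- numeric(0)
    for (arr in arrays) {
      if (has(arr, "MS:1000574"))
        stop("spectrum ", scan_id, ": zlib-compressed arrays not supported")
      bits64 <- has(arr, "MS:1000523")
      raw_b64 <- xml2::xml_text(xml2::xml_find_first(arr, ".//binary"))
      vals <- if (nzchar(raw_b64)) {
        readBin(jsonlite::base64_dec(raw_b64), "double", n = 1e7,
                size = if (bits64) 8L else 4L, endian = "little")
      } else numeric(0)
      if (has(arr, "MS:1000514")) mzs <- vals
      if (has(arr, "MS:1000515")) ints <- vals
    }
    spectra[[k]] <- new_spectrum(scan_id, ms_level, rt, mzs, ints,
                                 iso_c, iso_w)
  }
  run <- new_dia_run(spectra, run_id)
  if (demultiplex) run <- demultiplex_run(run, tol_ppm = tol_ppm)
  run
}

#' Write a DIA run as minimal mzML
#'
#' Emits uncompressed 64-bit arrays and minute-unit retention times; the
#' output is readable by \code{\link{read_mzml}}.
#' @param run a \code{DIARun}
#' @param path output file path
#' @return \code{path}, invisibly
#' @export
write_mzml <- function(run, path) {
  n <- length(run$spectra)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    '<?xml version="1.0" encoding="utf-8"?>',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">',
    sprintf('<run id="%s"><spectrumList count="%d">', run$run_id, n)), con)
  for (k in seq_len(n)) {
    s <- run$spectra[[k]]
    lines <- c(
      sprintf('<spectrum index="%d" id="%s" defaultArrayLength="%d">',
              k - 1L, s$scan_id, length(s$mzs)),
      sprintf('<cvParam accession="MS:1000511" name="ms level" value="%d"/>',
              s$ms_level),
      '<cvParam accession="MS:1000127" name="centroid spectrum"/>',
      sprintf('<scanList count="1"><scan><cvParam accession="MS:1000016" name="scan start time" value="%.8f" unitName="minute"/></scan></scanList>',
              s$rt))
    if (s$ms_level == 2L) {
      half <- s$isolation_width / 2
      lines <- c(lines, sprintf(paste0(
        '<precursorList count="1"><precursor><isolationWindow>',
        '<cvParam accession="MS:1000827" name="isolation window target m/z" value="%.8f"/>',
        '<cvParam accession="MS:1000828" name="isolation window lower offset" value="%.8f"/>',
        '<cvParam accession="MS:1000829" name="isolation window upper offset" value="%.8f"/>',
        '</isolationWindow></precursor></precursorList>'),
        s$isolation_center, half, half))
    }
    lines <- c(lines,
      '<binaryDataArrayList count="2">',
      '<binaryDataArray><cvParam accession="MS:1000523" name="64-bit float"/><cvParam accession="MS:1000576" name="no compression"/><cvParam accession="MS:1000514" name="m/z array"/>',
      sprintf('<binary>%s</binary></binaryDataArray>', b64_doubles_enc(s$mzs)),
      '<binaryDataArray><cvParam accession="MS:1000523" name="64-bit float"/><cvParam accession="MS:1000576" name="no compression"/><cvParam accession="MS:1000515" name="intensity array"/>',
      sprintf('<binary>%s</binary></binaryDataArray>', b64_doubles_enc(s$intensities)),
      '</binaryDataArrayList></spectrum>')
    writeLines(lines, con)
  }
  writeLines('</spectrumList></run></mzML>', con)
  invisible(path)
}

parse_msp_annotation <- function(txt) {
  # grammar: [by]<index>[^charge], e.g. "y5", "b3^2"; anything else -> NA
  m <- regmatches(txt, regexec("^\"?([by])([0-9]+)(\\^([0-9]+))?", txt))[[1]]
  if (length(m) == 0L)
    return(data.frame(type = NA_character_, index = NA_integer_,
                      charge = NA_integer_))
  data.frame(type = toupper(m[2]), index = as.integer(m[3]),
             charge = if (nzchar(m[5])) as.integer(m[5]) else 1L)
}

#' Read a NIST MSP spectrum library
#'
#' One \code{LibraryEntry} per Name block (peptide/charge). Fragment
#' correlation weights default to 1 (spectrum libraries carry no peak-shape
#' information). Unparseable blocks are skipped with a warning.
#' @param path MSP text file
#' @return a \code{PeptideLibrary} of target entries
#' @export
read_msp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^Name:", lines)
  if (!length(starts)) {
    warning("no entries found in MSP file ", path)
    return(new_library())
  }
  ends <- c(starts[-1L] - 1L, length(lines))
  entries <- list(); skipped <- 0L
  for (b in seq_along(starts)) {
    block <- lines[starts[b]:ends[b]]
    e <- tryCatch({
      name <- sub("^Name:\\s*", "", block[1L])
      parts <- strsplit(name, "/", fixed = TRUE)[[1L]]
      modseq <- parts[1L]
      charge <- if (length(parts) > 1L) as.integer(parts[2L]) else 2L
      comment <- grep("^Comment:", block, value = TRUE)
      rt <- NA_real_
      if (length(comment)) {
        m <- regmatches(comment[1L],
                        regexec("RetentionTime=([0-9.eE+-]+)", comment[1L]))[[1L]]
        if (length(m)) rt <- as.numeric(m[2L])
      }
      np_line <- grep("^Num [Pp]eaks:", block)
      npk <- as.integer(sub("^Num [Pp]eaks:\\s*", "", block[np_line[1L]]))
      peak_lines <- block[(np_line[1L] + 1L):length(block)]
      peak_lines <- peak_lines[nzchar(trimws(peak_lines))][seq_len(npk)]
      fields <- strsplit(trimws(peak_lines), "[\t ]+")
      mz <- vapply(fields, function(f) as.numeric(f[1L]), numeric(1))
      it <- vapply(fields, function(f) as.numeric(f[2L]), numeric(1))
      ann <- do.call(rbind, lapply(fields, function(f)
        if (length(f) >= 3L) parse_msp_annotation(f[3L])
        else data.frame(type = NA_character_, index = NA_integer_,
                        charge = NA_integer_)))
      if (anyNA(mz) || anyNA(it)) stop("bad peak line")
      new_library_entry(modseq, charge, rt, mz, it,
                        fragment_annotations = ann)
    }, error = function(err) NULL)
    if (is.null(e)) skipped <- skipped + 1L else entries[[length(entries) + 1L]] <- e
  }
  if (skipped > 0L)
    warning(skipped, " unparseable MSP block(s) skipped in ", path)
  new_library(entries)
}

SQLITE_SCHEMA_VERSION <- "1"

#' Write a peptide library to the package's SQLite format
#'
#' Schema: \code{meta(key, value)}, \code{entries(modseq, charge,
#' precursor_mz, rt_sec, is_decoy, source, mz, intensity, correlation,
#' annotation)} with arrays stored as little-endian float64 BLOBs
#' (annotations as a JSON BLOB), and \code{peptide_protein(modseq,
#' accession)}. Not byte-compatible with any vendor library format.
#' @param lib a \code{PeptideLibrary}
#' @param path output SQLite file
#' @return \code{path}, invisibly
#' @export
write_sqlite_library <- function(lib, path) {
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  on.exit(DBI::dbDisconnect(con))
  DBI::dbExecute(con, "DROP TABLE IF EXISTS meta")
  DBI::dbExecute(con, "DROP TABLE IF EXISTS entries")
  DBI::dbExecute(con, "DROP TABLE IF EXISTS peptide_protein")
  DBI::dbExecute(con, "CREATE TABLE meta (key TEXT PRIMARY KEY, value TEXT)")
  DBI::dbExecute(con,
    "CREATE TABLE entries (modseq TEXT, charge INT, precursor_mz REAL,
     rt_sec REAL, is_decoy INT, source TEXT, mz BLOB, intensity BLOB,
     correlation BLOB, annotation BLOB)")
  DBI::dbExecute(con,
    "CREATE TABLE peptide_protein (modseq TEXT, accession TEXT)")
  DBI::dbExecute(con, "INSERT INTO meta VALUES ('schema_version', ?)",
                 params = list(SQLITE_SCHEMA_VERSION))
  as_blob <- function(x) list(writeBin(as.numeric(x), raw(), size = 8L,
                                       endian = "little"))
  rows <- lapply(lib$entries, function(e) {
    data.frame(
      modseq = e$peptide_modseq, charge = e$charge,
      precursor_mz = e$precursor_mz, rt_sec = e$library_rt * 60,
      is_decoy = as.integer(e$is_decoy), source = e$source,
      mz = I(as_blob(e$fragment_mzs)),
      intensity = I(as_blob(e$fragment_intensities)),
      correlation = I(as_blob(e$fragment_correlations)),
      annotation = I(list(charToRaw(jsonlite::toJSON(e$fragment_annotations))))
    )
  })
  if (length(rows))
    DBI::dbAppendTable(con, "entries", do.call(rbind, rows))
  if (nrow(lib$protein_map))
    DBI::dbAppendTable(con, "peptide_protein", lib$protein_map)
  invisible(path)
}

#' Read a peptide library from the package's SQLite format
#' @param path SQLite file written by \code{\link{write_sqlite_library}}
#' @return a \code{PeptideLibrary}
#' @export
read_sqlite_library <- function(path) {
  con <- tryCatch(DBI::dbConnect(RSQLite::SQLite(), path),
                  error = function(e) stop("cannot open SQLite file ", path))
  on.exit(DBI::dbDisconnect(con))
  tabs <- tryCatch(DBI::dbListTables(con),
                   error = function(e) stop(path, " is not a SQLite database"))
  if (!"meta" %in% tabs) stop(path, " is not a SQLite database with a meta table")
  ver <- DBI::dbGetQuery(con,
    "SELECT value FROM meta WHERE key = 'schema_version'")$value
  if (!identical(ver, SQLITE_SCHEMA_VERSION))
    stop("library schema version mismatch: expected ", SQLITE_SCHEMA_VERSION,
         ", found ", if (length(ver)) ver else "<none>")
  df <- DBI::dbGetQuery(con, "SELECT * FROM entries")
  from_blob <- function(b)
    readBin(b, "double", n = length(b) %/% 8L, size = 8L, endian = "little")
  entries <- lapply(seq_len(nrow(df)), function(i) {
    ann <- jsonlite::fromJSON(rawToChar(df$annotation[[i]]))
    if (length(ann) == 0L || is.null(dim(ann))) ann <- NULL
    new_library_entry(
      df$modseq[i], df$charge[i], df$rt_sec[i] / 60,
      from_blob(df$mz[[i]]), from_blob(df$intensity[[i]]),
      from_blob(df$correlation[[i]]),
      fragment_annotations = ann,
      is_decoy = df$is_decoy[i] == 1L, source = df$source[i],
      precursor_mz = df$precursor_mz[i])
  })
  pm <- DBI::dbGetQuery(con, "SELECT * FROM peptide_protein")
  new_library(entries, pm)
}

#' Tryptic in-silico digestion of a FASTA database
#'
#' Cleaves after K/R except before P, keeps peptides of length 5-50, and
#' returns the peptide-to-protein map. Duplicate accessions warn and the
#' last sequence wins.
#' @param path FASTA file of protein sequences
#' @param missed_cleavages maximum missed cleavages (0-2 typical)
#' @return data.frame with columns \code{modseq} (bare peptide sequence)
#'   and \code{accession}
#' @export
digest_fasta <- function(path, missed_cleavages = 0L) {
  aa <- Biostrings::readAAStringSet(path)
  if (!length(aa)) stop("no FASTA records in ", path)
  acc <- sub("^\\s*(\\S+).*$", "\\1", names(aa))
  seqs <- toupper(as.character(aa))
  if (anyDuplicated(acc)) {
    warning("duplicate FASTA accession(s): ",
            paste(unique(acc[duplicated(acc)]), collapse = ", "),
            "; last sequence wins")
    keep <- !duplicated(acc, fromLast = TRUE)
    acc <- acc[keep]; seqs <- seqs[keep]
  }
  out <- vector("list", length(acc))
  for (i in seq_along(acc)) {
    out[[i]] <- data.frame(modseq = digest_sequence(seqs[i], missed_cleavages),
                           accession = acc[i])
  }
  res <- unique(do.call(rbind, out))
  rownames(res) <- NULL
  res
}

digest_sequence <- function(seq, missed_cleavages = 0L,
                            min_len = 5L, max_len = 50L) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  if (n == 0L) return(character(0))
  cut_after <- which(chars %in% c("K", "R"))
  cut_after <- cut_after[cut_after < n & chars[pmin(cut_after + 1L, n)] != "P" |
                           cut_after == n]
  bounds <- c(0L, cut_after, if (!n %in% cut_after) n)
  bounds <- sort(unique(bounds))
  peps <- character(0)
  nb <- length(bounds)
  for (i in seq_len(nb - 1L)) {
    for (mc in 0:missed_cleavages) {
      j <- i + 1L + mc
      if (j > nb) break
      p <- substr(seq, bounds[i] + 1L, bounds[j])
      if (nchar(p) >= min_len && nchar(p) <= max_len) peps <- c(peps, p)
    }
  }
  unique(peps)
}
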