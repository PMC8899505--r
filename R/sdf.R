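# MDL SDF V2000 input/output. Gzip input is detected from the magic bytes.
# Bond order 4 in the bond block is interpreted as aromatic and kekulized on
# load; the MDL data block ("> <NAME>" lines) is captured verbatim per record.

#' Read molecules from an MDL SDF (V2000)
#'
#' @param source path to an `.sdf` or gzip-compressed `.sdf.gz` file, or a
#'   character vector of lines.
#' @param strict if `FALSE` (default) unparseable records are skipped with a
#'   warning; if `TRUE` they raise an error naming the record index.
#' @return list of [molecule()] objects, one per `$$$$`-terminated record.
#' @export
read_sdf <- function(source, strict = FALSE) {
  lines <- if (length(source) == 1L && file.exists(source)) {
    con <- if (is_gzip(source)) gzfile(source, "rt") else file(source, "rt")
    on.exit(close(con))
    readLines(con, warn = FALSE)
  } else as.character(source)
  if (!length(lines)) return(list())
  # split records on $$$$
  ends <- which(trimws(lines) == "$$$$")
  starts <- c(1L, head(ends, -1L) + 1L)
  if (!length(ends)) {
    if (all(!nzchar(trimws(lines)))) return(list())
    ends <- length(lines); starts <- 1L
  }
  mols <- list()
  for (r in seq_along(ends)) {
    rec <- lines[starts[r]:(ends[r] - 1L)]
    if (all(!nzchar(trimws(rec)))) next
    mol <- tryCatch(parse_sdf_record(rec),
                    error = function(e) {
                      msg <- sprintf("SDF record %d: %s", r, conditionMessage(e))
                      if (strict) stop(msg, call. = FALSE)
                      warning(msg, call. = FALSE)
                      NULL
                    })
    if (!is.null(mol)) mols[[length(mols) + 1L]] <- mol
  }
  mols
}

is_gzip <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 2L)
  length(magic) == 2L && magic[1] == as.raw(0x1f) && magic[2] == as.raw(0x8b)
}

parse_sdf_record <- function(rec) {
  if (length(rec) < 4L) stop("record too short")
  name <- trimws(rec[1])
  counts <- rec[4]
  if (grepl("V3000", counts)) stop("V3000 records are not supported")
  na <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  nb <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(na) || is.na(nb) || na < 0L)
    stop("malformed counts line: ", sQuote(counts))
  if (length(rec) < 4L + na + nb) stop("truncated atom/bond block")
  atoms <- data.frame(element = character(na), charge = integer(na),
                      x = numeric(na), y = numeric(na), z = numeric(na),
                      aromatic = logical(na), stringsAsFactors = FALSE)
  for (i in seq_len(na)) {
    ln <- rec[4L + i]
    atoms$x[i] <- as.numeric(substr(ln, 1, 10))
    atoms$y[i] <- as.numeric(substr(ln, 11, 20))
    atoms$z[i] <- as.numeric(substr(ln, 21, 30))
    atoms$element[i] <- trimws(substr(ln, 32, 34))
    cc <- suppressWarnings(as.integer(substr(ln, 37, 39)))
    # old-style charge column: 0 none, 1 -> +3 ... 3 -> +1, 4 -> radical,
    # 5 -> -1 ... 7 -> -3
    atoms$charge[i] <- if (is.na(cc) || cc == 0L || cc == 4L) 0L else 4L - cc
  }
  bonds <- NULL
  if (nb > 0L) {
    bonds <- data.frame(a1 = integer(nb), a2 = integer(nb),
                        order = integer(nb), stringsAsFactors = FALSE)
    for (k in seq_len(nb)) {
      ln <- rec[4L + na + k]
      bonds$a1[k] <- as.integer(substr(ln, 1, 3))
      bonds$a2[k] <- as.integer(substr(ln, 4, 6))
      bonds$order[k] <- as.integer(substr(ln, 7, 9))
    }
    if (anyNA(bonds)) stop("malformed bond block")
  }
  # properties block: M  CHG overrides atom charges; data block after M  END
  props <- list()
  tail_lines <- if (length(rec) > 4L + na + nb)
    rec[(5L + na + nb):length(rec)] else character()
  i <- 1L
  while (i <= length(tail_lines)) {
    ln <- tail_lines[i]
    if (startsWith(ln, "M  CHG")) {
      nn <- as.integer(substr(ln, 7, 9))
      rest <- scan(text = substring(ln, 10), what = integer(), quiet = TRUE)
      for (m in seq_len(nn))
        atoms$charge[rest[2 * m - 1L]] <- rest[2 * m]
    } else if (startsWith(ln, "> ")) {
      pname <- sub("^>\\s*<([^>]*)>.*$", "\\1", ln)
      vals <- character()
      i <- i + 1L
      while (i <= length(tail_lines) && nzchar(trimws(tail_lines[i]))) {
        vals <- c(vals, tail_lines[i])
        i <- i + 1L
      }
      props[[pname]] <- paste(vals, collapse = "\n")
    }
    i <- i + 1L
  }
  aromatic_in <- !is.null(bonds) && any(bonds$order == 4L)
  mol <- molecule(name, atoms, bonds, props, perceive = !aromatic_in)
  if (aromatic_in) mol <- kekulize(mol)
  mol
}

#' Write molecules to an MDL SDF (V2000)
#'
#' Output is kekulized (bond orders 1/2/3) by default; with
#' `explicit_aromaticity` aromatic bonds are written as order 4. MDL
#' properties are preserved in order.
#'
#' @param mols a `molecule` or list of molecules.
#' @param path output file; `.gz` suffix writes gzip. If `NULL`, the SDF text
#'   is returned as a character vector of lines.
#' @param explicit_aromaticity write aromatic bonds as order 4.
#' @return invisibly, the lines written (or the lines themselves if
#'   `path = NULL`).
#' @export
write_sdf <- function(mols, path = NULL, explicit_aromaticity = FALSE) {
  if (inherits(mols, "molecule")) mols <- list(mols)
  out <- unlist(lapply(mols, format_sdf_record,
                       explicit_aromaticity = explicit_aromaticity))
  if (is.null(path)) return(out)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(out, con)
  invisible(out)
}

format_sdf_record <- function(mol, explicit_aromaticity = FALSE) {
  na <- n_atoms(mol); nb <- nrow(mol$bonds)
  header <- c(mol$name, "  chemtk", "")
  counts <- sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nb)
  atom_lines <- vapply(seq_len(na), function(i) {
    sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
            mol$atoms$x[i], mol$atoms$y[i], mol$atoms$z[i],
            mol$atoms$element[i])
  }, character(1))
  bond_lines <- character()
  if (nb > 0L) {
    ord <- mol$bonds$order
    if (explicit_aromaticity) ord[mol$bonds$aromatic] <- 4L
    else if (any(ord > 3L)) {
      ring_atoms <- sort(unique(c(mol$bonds$a1[ord > 3L],
                                  mol$bonds$a2[ord > 3L])))
      stop("non-kekulizable aromatic system over atoms ",
           paste(ring_atoms, collapse = ", "))
    }
    bond_lines <- vapply(seq_len(nb), function(k) {
      sprintf("%3d%3d%3d  0  0  0  0", mol$bonds$a1[k], mol$bonds$a2[k],
              ord[k])
    }, character(1))
  }
  chg <- which(mol$atoms$charge != 0L)
  chg_lines <- if (length(chg)) {
    vapply(split(chg, ceiling(seq_along(chg) / 8)), function(grp) {
      paste0(sprintf("M  CHG%3d", length(grp)),
             paste0(sprintf("%4d%4d", grp, mol$atoms$charge[grp]),
                    collapse = ""))
    }, character(1))
  } else character()
  prop_lines <- character()
  for (pname in names(mol$properties)) {
    prop_lines <- c(prop_lines, sprintf(">  <%s>", pname),
                    strsplit(as.character(mol$properties[[pname]]),
                             "\n", fixed = TRUE)[[1]], "")
  }
  c(header, counts, atom_lines, bond_lines, chg_lines, "M  END",
    prop_lines, "$$$$")
}
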