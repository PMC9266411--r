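#' Read / write 3-column SAS ASCII files
#'
#' Plain-text (q, I, sigma) profiles with `#` comment lines, the common
#' small-angle-scattering exchange dialect.  q is stored in 1/Angstrom;
#' files in 1/nm are converted on read with `q_unit = "nm"` (factor 0.1).
#'
#' @param file path
#' @param q_unit `"A"` (default, 1/Angstrom) or `"nm"` (1/nm, converted)
#' @param meta metadata list attached to the curve
#' @return a [scattering_curve()]
#' @export
read_sas <- function(file, q_unit = c("A", "nm"), meta = list()) {
  q_unit <- match.arg(q_unit)
  d <- .read_numeric_table(file, 3)
  q <- d[, 1] * if (q_unit == "nm") 0.1 else 1
  scattering_curve(q, d[, 2], d[, 3], meta = c(meta, list(source = file)))
}

#' @rdname read_sas
#' @param curve a [scattering_curve()]
#' @param header extra comment lines written at the top
#' @export
write_sas <- function(curve, file, header = character()) {
  stopifnot(inherits(curve, "scattering_curve"))
  lines <- c(paste0("# ", c("q[1/A] I sigma", header)),
             sprintf("%.8g %.8g %.8g", curve$q, curve$I, curve$sigma))
  writeLines(lines, file)
  invisible(file)
}

.read_numeric_table <- function(file, ncol_expect) {
  lines <- readLines(file)
  keep <- !grepl("^\\s*(#|$)", lines)
  rows <- which(keep)
  if (!length(rows)) stop("no data lines in ", file)
  parts <- strsplit(trimws(lines[keep]), "\\s+")
  nc <- lengths(parts)
  if (any(nc != ncol_expect))
    stop(sprintf("%s: line %d has %d columns, expected %d",
                 file, rows[which(nc != ncol_expect)[1]],
                 nc[nc != ncol_expect][1], ncol_expect))
  vals <- suppressWarnings(as.numeric(unlist(parts)))
  if (anyNA(vals)) {
    bad <- which(vapply(parts, function(p) anyNA(suppressWarnings(as.numeric(p))), TRUE))[1]
    stop(sprintf("%s: line %d is not numeric", file, rows[bad]))
  }
  matrix(vals, ncol = ncol_expect, byrow = TRUE)
}

#' Read / write NSE relaxation spectra
#'
#' Four-column ASCII (q \[1/Angstrom\], t \[ns\], I(q,t)/I(q,0), sigma).
#' The reader also accepts blocked files where `# q=<value>` headers
#' precede 3-column (t, I/I0, sigma) blocks.
#'
#' @param file path
#' @param T,eta condition metadata stored on the dataset
#' @param q_unit `"A"` or `"nm"`
#' @return an [nse_dataset()]
#' @export
read_nse <- function(file, T = 295, eta = 1.1, q_unit = c("A", "nm")) {
  q_unit <- match.arg(q_unit)
  fac <- if (q_unit == "nm") 0.1 else 1
  lines <- readLines(file)
  qhead <- grepl("^\\s*#\\s*q\\s*=", lines)
  if (any(qhead)) {
    cur_q <- NA_real_
    rows <- list()
    for (i in seq_along(lines)) {
      ln <- lines[i]
      if (qhead[i]) {
        cur_q <- as.numeric(sub("^\\s*#\\s*q\\s*=\\s*([0-9.eE+-]+).*", "\\1", ln))
        next
      }
      if (grepl("^\\s*(#|$)", ln)) next
      v <- suppressWarnings(as.numeric(strsplit(trimws(ln), "\\s+")[[1]]))
      if (length(v) != 3 || anyNA(v))
        stop(sprintf("%s: line %d: expected 3 numeric columns in q-block", file, i))
      if (is.na(cur_q)) stop(sprintf("%s: data before first '# q=' header", file))
      rows[[length(rows) + 1]] <- c(cur_q, v)
    }
    d <- do.call(rbind, rows)
  } else {
    d <- .read_numeric_table(file, 4)
  }
  nse_dataset(d[, 1] * fac, d[, 2], d[, 3], d[, 4], T = T, eta = eta,
              meta = list(source = file))
}

#' @rdname read_nse
#' @param ds an [nse_dataset()]
#' @param header extra comment lines
#' @export
write_nse <- function(ds, file, header = character()) {
  stopifnot(inherits(ds, "nse_dataset"))
  d <- ds$data
  lines <- c(paste0("# ", c("q[1/A] t[ns] I/I0 sigma", header)),
             sprintf("%.8g %.8g %.8g %.8g", d$q, d$t, d$fnorm, d$sigma))
  writeLines(lines, file)
  invisible(file)
}

#' Read / write coarse-grained ensembles as CA-only PDB
#'
#' Conformers are stored as MODEL/ENDMDL blocks of CA atoms with 1-based
#' residue numbering; the occupancy column carries the population weight of
#' the model (repeated on every atom of the model).
#'
#' @param ens a [bead_ensemble()]
#' @param file path
#' @return for the reader: a [bead_ensemble()]
#' @export
write_pdb_ensemble <- function(ens, file) {
  stopifnot(inherits(ens, "bead_ensemble"))
  con <- file(file, "w")
  on.exit(close(con))
  for (ic in seq_along(ens$chains)) {
    ch <- ens$chains[[ic]]
    writeLines(sprintf("MODEL     %4d", ic), con)
    xyz <- ch$coords
    writeLines(sprintf(
      "ATOM  %5d  CA  GLY A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
      seq_len(nrow(xyz)), seq_len(nrow(xyz)),
      xyz[, 1], xyz[, 2], xyz[, 3], ens$weights[ic], 0), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(file)
}

#' @rdname write_pdb_ensemble
#' @param bond nominal bond length passed to [bead_chain()]
#' @export
read_pdb_ensemble <- function(file, bond = 3.8) {
  lines <- readLines(file)
  chains <- list()
  weights <- numeric()
  cur <- NULL
  w <- 1
  flush <- function() {
    if (!is.null(cur) && nrow(cur)) {
      chains[[length(chains) + 1]] <<- bead_chain(cur, bond = bond)
      weights[length(weights) + 1] <<- w
    }
    cur <<- NULL
  }
  for (ln in lines) {
    rec <- substr(ln, 1, 6)
    if (rec == "MODEL ") { flush(); cur <- matrix(0, 0, 3); w <- 1 }
    else if (rec == "ENDMDL") flush()
    else if (rec %in% c("ATOM  ", "HETATM")) {
      if (trimws(substr(ln, 13, 16)) != "CA") next
      if (is.null(cur)) cur <- matrix(0, 0, 3)
      cur <- rbind(cur, as.numeric(c(substr(ln, 31, 38), substr(ln, 39, 46),
                                     substr(ln, 47, 54))))
      w <- as.numeric(substr(ln, 55, 60))
      if (is.na(w)) w <- 1
    }
  }
  flush()
  if (!length(chains)) stop("no CA models found in ", file)
  bead_ensemble(chains, weights)
}
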