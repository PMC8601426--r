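#' Read a single-cell Hi-C pairs file
#'
#' Tab-separated records `chrom1 pos1 chrom2 pos2` (extra columns ignored);
#' `#` lines are comments. Malformed lines (too few fields or non-numeric
#' positions) are skipped with a warning carrying the count.
#'
#' @param path file path.
#' @return data.frame with columns `chrom1, pos1, chrom2, pos2`; attribute
#'   `nMalformed` holds the skipped-line count.
#' @export
readPairs <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(trimws(lines), "#")]
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    out <- data.frame(chrom1 = character(), pos1 = numeric(),
                      chrom2 = character(), pos2 = numeric())
    attr(out, "nMalformed") <- 0L
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ok <- lengths(fields) >= 4
  p1 <- suppressWarnings(as.numeric(vapply(fields, function(f)
    if (length(f) >= 4) f[2] else NA_character_, "")))
  p2 <- suppressWarnings(as.numeric(vapply(fields, function(f)
    if (length(f) >= 4) f[4] else NA_character_, "")))
  ok <- ok & !is.na(p1) & !is.na(p2)
  nBad <- sum(!ok)
  if (nBad) warning("readPairs: skipped ", nBad, " malformed line(s)")
  out <- data.frame(
    chrom1 = vapply(fields[ok], `[`, "", 1), pos1 = p1[ok],
    chrom2 = vapply(fields[ok], `[`, "", 3), pos2 = p2[ok],
    stringsAsFactors = FALSE)
  attr(out, "nMalformed") <- nBad
  out
}

#' Read a UCSC chrom.sizes file
#'
#' @param path 2-column TSV of chromosome name and length.
#' @return data.frame with columns `chrom, length`.
#' @export
readChromSizes <- function(path) {
  d <- read.table(path, sep = "\t", header = FALSE,
                  col.names = c("chrom", "length"),
                  colClasses = c("character", "numeric"))
  d
}

provenance_comment <- function(seed = NULL) {
  paste0("DPDfold ", packageVersion("DPDfold"),
         if (!is.null(seed)) paste0(" seed=", seed) else "",
         " ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
}

#' Write a conformation as XYZ
#'
#' One frame: bead count, a provenance comment line, then one
#' `element x y z [chain]` line per bead (element `P`; the optional fifth
#' column is the chain index).
#'
#' @param conf a [Conformation].
#' @param path output file.
#' @param chainColumn append a per-bead chain index column.
#' @param digits coordinate precision.
#' @return `path`, invisibly.
#' @export
writeXYZ <- function(conf, path, chainColumn = FALSE, digits = 6) {
  co <- conf@coords
  n <- nrow(co)
  fmt <- paste0("%.", digits, "f")
  lines <- sprintf(paste("P", fmt, fmt, fmt), co[, 1], co[, 2], co[, 3])
  if (chainColumn) {
    ch <- conf@chains
    chainOf <- integer(n)
    for (c in seq_along(ch))
      chainOf[IRanges::start(ch)[c]:IRanges::end(ch)[c]] <- c
    lines <- paste(lines, chainOf)
  }
  writeLines(c(as.character(n), provenance_comment(), lines), path)
  invisible(path)
}

#' Read an XYZ conformation
#'
#' @param path XYZ file; a fifth column, when present, is taken as the chain
#'   index.
#' @return a [Conformation].
#' @export
readXYZ <- function(path) {
  lines <- readLines(path)
  n <- as.integer(lines[1])
  body <- strsplit(trimws(lines[3:(2 + n)]), "\\s+")
  co <- t(vapply(body, function(f) as.numeric(f[2:4]), numeric(3)))
  chains <- NULL
  if (all(lengths(body) >= 5)) {
    chainOf <- vapply(body, function(f) as.integer(f[5]), 1L)
    idx <- which(diff(chainOf) != 0)
    chains <- IRanges::IRanges(c(1L, idx + 1L), c(idx, n))
  }
  Conformation(co, chains = chains)
}

#' Write a conformation as a pseudo-atom PDB
#'
#' Each bead becomes a CA pseudo-atom; each polymer chain gets its own chain
#' identifier. Coordinates are multiplied by 10 per DPD length unit (stated
#' in a REMARK) so default viewer bond/clash heuristics behave.
#'
#' @param conf a [Conformation] with at most 62 chains.
#' @param path output file.
#' @param scale viewer scale factor per DPD length unit.
#' @return `path`, invisibly.
#' @export
writePDB <- function(conf, path, scale = 10) {
  ch <- conf@chains
  if (length(ch) > 62)
    stop("PDB chain identifiers support at most 62 chains; use writeXYZ()")
  ids <- c(LETTERS, letters, as.character(0:9))
  co <- conf@coords * scale
  out <- c(sprintf("REMARK     coordinates scaled by %g per DPD length unit",
                   scale),
           paste0("REMARK     ", provenance_comment()))
  serial <- 0L
  for (c in seq_along(ch)) {
    beads <- IRanges::start(ch)[c]:IRanges::end(ch)[c]
    resseq <- 0L
    for (b in beads) {
      serial <- serial + 1L
      resseq <- resseq + 1L
      out <- c(out, sprintf(
        "ATOM  %5d  CA  GLY %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
        serial %% 100000L, ids[c], resseq %% 10000L,
        co[b, 1], co[b, 2], co[b, 3]))
    }
    out <- c(out, "TER")
  }
  writeLines(c(out, "END"), path)
  invisible(path)
}

#' Write / read a contact map as TSV
#'
#' Two columns of 1-based bead indices with a `# n_beads=<n>` header line.
#'
#' @param cmap a [ContactMap].
#' @param path file path.
#' @return `path` (writer, invisibly) / a [ContactMap] (reader).
#' @export
writeContactMap <- function(cmap, path) {
  hdr <- paste0("# n_beads=", cmap@nBeads)
  body <- if (nrow(cmap@pairs)) {
    m <- cmap@pairs
    if (length(cmap@multiplicity))
      paste(m[, 1], m[, 2], cmap@multiplicity, sep = "\t")
    else paste(m[, 1], m[, 2], sep = "\t")
  } else character()
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname writeContactMap
#' @export
readContactMap <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#\\s*n_beads=", lines, value = TRUE)
  if (!length(hdr)) stop("missing '# n_beads=' header")
  n <- as.integer(sub(".*n_beads=\\s*", "", hdr[1]))
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(body)) return(ContactMap(matrix(integer(), 0, 2), n))
  f <- strsplit(body, "\t", fixed = TRUE)
  i <- as.integer(vapply(f, `[`, "", 1))
  j <- as.integer(vapply(f, `[`, "", 2))
  mult <- if (all(lengths(f) >= 3)) as.integer(vapply(f, `[`, "", 3)) else NULL
  ContactMap(cbind(i, j), n, multiplicity = mult)
}

#' Write / read a dense distance map
#'
#' Whitespace-delimited matrix; missing entries are `NaN`.
#'
#' @param dmap a [DistanceMap].
#' @param path file path.
#' @return `path` (writer, invisibly) / a [DistanceMap] (reader).
#' @export
writeDistanceMap <- function(dmap, path) {
  v <- dmap@values
  if (!is.null(dmap@mask)) v[!dmap@mask] <- NaN
  write.table(format(v, digits = 8, trim = TRUE), path, sep = " ",
              row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeDistanceMap
#' @export
readDistanceMap <- function(path) {
  v <- as.matrix(read.table(path, header = FALSE))
  dimnames(v) <- NULL
  asDistanceMap(v)
}
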