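#' Read an expression matrix from TSV
#'
#' Expected layout: first column holds probe/gene identifiers, remaining
#' columns are samples (header row = sample IDs). Values are numeric.
#'
#' @param path file path.
#' @param species optional species tag stored as an attribute.
#' @return numeric matrix (rows = genes/probes, columns = samples) with a
#'   `species` attribute.
#' @export
read_expression_tsv <- function(path, species = NA_character_) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  ids <- as.character(dt[[1L]])
  m <- as.matrix(dt[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  attr(m, "species") <- species
  m
}

#' Write an expression matrix to TSV
#'
#' @param m numeric matrix with rownames (gene/probe IDs) and colnames
#'   (sample IDs).
#' @param path output file.
#' @param id_col name of the identifier column (default "id").
#' @export
write_expression_tsv <- function(m, path, id_col = "id") {
  dt <- data.table::data.table(id = rownames(m))
  data.table::setnames(dt, "id", id_col)
  dt <- cbind(dt, data.table::as.data.table(m))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Read an ortholog map TSV (columns: ref_gene, test_gene)
#' @param path file path.
#' @return data.frame with columns ref_gene, test_gene.
#' @export
read_ortholog_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                          colClasses = "character")
  names(dt)[1:2] <- c("ref_gene", "test_gene")
  dt
}

#' Read a SNP/gene position table (1-based inclusive coordinates)
#'
#' Columns: id, chrom, start, end. SNP tables may carry start == end.
#' @param path file path.
#' @return data.frame with columns id, chrom, start, end.
#' @export
read_positions_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  names(dt)[1:4] <- c("id", "chrom", "start", "end")
  dt$id <- as.character(dt$id)
  dt$chrom <- as.character(dt$chrom)
  stopifnot(all(dt$start <= dt$end))
  dt
}

#' Read a dosage matrix from TSV (rows = SNPs, columns = samples)
#' @param path file path.
#' @return numeric matrix of dosages in [0, 2].
#' @export
read_dosage_tsv <- function(path) {
  m <- read_expression_tsv(path)
  attr(m, "species") <- NULL
  if (any(m < 0 | m > 2, na.rm = TRUE))
    stop("dosages outside [0, 2] in ", path)
  m
}

#' Read per-genotype dosages (DS FORMAT field) from a plain-text VCF
#'
#' Minimal reader for uncompressed VCF 4.x with a `DS` entry in FORMAT.
#' Only the fields needed for an eQTL scan are retained.
#'
#' @param path VCF file path.
#' @return list with `dosage` (SNP x sample matrix) and `positions`
#'   (data.frame id, chrom, start, end).
#' @export
read_dosage_vcf <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  hdr <- grep("^#CHROM", lines)
  if (length(hdr) != 1L) stop("no #CHROM header line in ", path)
  cols <- strsplit(sub("^#", "", lines[hdr]), "\t", fixed = TRUE)[[1L]]
  if (length(cols) < 10L) stop("VCF has no genotype columns")
  samples <- cols[-(1:9)]
  body <- lines[-seq_len(hdr)]
  body <- body[!startsWith(body, "#")]
  fields <- strsplit(body, "\t", fixed = TRUE)
  n <- length(fields)
  dos <- matrix(NA_real_, n, length(samples))
  ids <- character(n)
  chrom <- character(n)
  pos <- integer(n)
  for (i in seq_len(n)) {
    f <- fields[[i]]
    chrom[i] <- f[1L]
    pos[i] <- as.integer(f[2L])
    ids[i] <- if (f[3L] == ".") paste0(f[1L], ":", f[2L]) else f[3L]
    fmt <- strsplit(f[9L], ":", fixed = TRUE)[[1L]]
    k <- match("DS", fmt)
    if (is.na(k)) stop("no DS entry in FORMAT at record ", i)
    gt <- strsplit(f[-(1:9)], ":", fixed = TRUE)
    dos[i, ] <- vapply(gt, function(g) as.numeric(g[k]), numeric(1))
  }
  rownames(dos) <- ids
  colnames(dos) <- samples
  list(dosage = dos,
       positions = data.frame(id = ids, chrom = chrom, start = pos, end = pos,
                              stringsAsFactors = FALSE))
}

#' Read a covariate table (rows = samples, columns = covariates)
#' @param path file path; first column = sample ID.
#' @return numeric matrix with sample rownames.
#' @export
read_covariates_tsv <- function(path) {
  m <- read_expression_tsv(path)
  attr(m, "species") <- NULL
  m
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then member genes, tab-separated.
#' @param path GMT file path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[`, character(1), 1L)
  sets
}

#' Write gene sets in GMT format
#' @param sets named list of character vectors.
#' @param path output file.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
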