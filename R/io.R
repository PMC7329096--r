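#' Read a genotype table
#'
#' Two dialects are supported.
#'
#' **tabular**: UTF-8, comma- or tab-delimited (auto-detected from the header
#' line), header `name,group,<locus>_1,<locus>_2,...,<cplocus>`. Each nuclear
#' locus occupies two adjacent columns suffixed `_1`/`_2`; any remaining
#' single columns are haploid chloroplast loci. Missing calls may be encoded
#' as `0` or an empty field.
#'
#' **genalex**: the GenAlEx codominant layout. Row 1: number of nuclear loci,
#' number of samples, number of populations, then one size per population.
#' Row 2: dataset title followed by the population names. Row 3: sample and
#' population column headers, then one header per nuclear locus (second
#' allele column left blank), then one header per chloroplast locus. Data
#' rows follow. Chloroplast loci are an extension of the layout: single
#' haploid columns appended after the codominant block (the locus count in
#' row 1 refers to nuclear loci only). Population sizes in the header are
#' validated as totals, so groups need not be contiguous and a write/read
#' round trip preserves row order exactly.
#'
#' @param path file to read.
#' @param dialect `"tabular"` or `"genalex"`.
#' @return A [genotype_matrix()].
#' @seealso [write_genotypes()]
#' @export
read_genotypes <- function(path, dialect = c("tabular", "genalex")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!grepl("^\\s*$", lines)]
  if (dialect == "tabular") read_tabular(lines, path) else read_genalex(lines, path)
}

detect_sep <- function(header) if (grepl("\t", header)) "\t" else ","

split_fields <- function(lines, sep) {
  lapply(strsplit(lines, sep, fixed = TRUE), trimws)
}

# parse one allele field; "" and "0" are the missing codes
parse_allele <- function(x, row, col, path) {
  x[x == "" | is.na(x)] <- "0"
  suppressWarnings(v <- as.integer(x))
  frac <- suppressWarnings(as.numeric(x))
  bad <- is.na(v) | (!is.na(frac) & frac != floor(frac))
  if (any(bad)) {
    i <- which(bad)[1]
    stop("non-integer allele value ", sQuote(x[i]), " at data row ", row[i],
         ", column ", col[i], " of ", path)
  }
  v[v == 0L] <- NA_integer_
  v
}

read_tabular <- function(lines, path) {
  if (length(lines) < 1) stop("malformed header: empty file ", path)
  sep <- detect_sep(lines[1])
  rows <- split_fields(lines, sep)
  header <- rows[[1]]
  if (length(header) < 2 || tolower(header[1]) != "name" ||
      tolower(header[2]) != "group") {
    stop("malformed header in ", path,
         ": expected columns starting `name,group`")
  }
  locus_cols <- header[-(1:2)]
  is_pair <- grepl("_[12]$", locus_cols)
  base <- sub("_[12]$", "", locus_cols)
  nuc_names <- unique(base[is_pair])
  for (nm in nuc_names) {
    idx <- which(base == nm & is_pair)
    if (length(idx) != 2 ||
        !identical(locus_cols[idx], paste0(nm, c("_1", "_2")))) {
      stop("malformed header in ", path, ": nuclear locus ", nm,
           " must have adjacent columns ", nm, "_1 and ", nm, "_2")
    }
  }
  cp_names <- locus_cols[!is_pair]
  ncol_expected <- length(header)
  data <- rows[-1]
  n <- length(data)
  # a trailing empty field (missing code) is dropped by the splitter; pad
  data <- lapply(data, function(r)
    if (length(r) < ncol_expected) c(r, rep("", ncol_expected - length(r)))
    else r)
  bad_len <- which(vapply(data, length, 1L) != ncol_expected)
  if (length(bad_len)) {
    stop("row ", bad_len[1] + 1, " of ", path, " has ",
         length(data[[bad_len[1]]]), " fields; expected ", ncol_expected)
  }
  mat <- if (n) do.call(rbind, data) else
    matrix(character(0), 0, ncol_expected)
  ind <- data.frame(name = mat[, 1], group = mat[, 2],
                    stringsAsFactors = FALSE)
  nuc <- array(NA_integer_, dim = c(n, length(nuc_names), 2),
               dimnames = list(NULL, nuc_names, NULL))
  for (j in seq_along(nuc_names)) {
    c1 <- 2 + which(locus_cols == paste0(nuc_names[j], "_1"))
    c2 <- 2 + which(locus_cols == paste0(nuc_names[j], "_2"))
    nuc[, j, 1] <- parse_allele(mat[, c1], seq_len(n), rep(c1, n), path)
    nuc[, j, 2] <- parse_allele(mat[, c2], seq_len(n), rep(c2, n), path)
  }
  cp <- matrix(NA_integer_, n, length(cp_names),
               dimnames = list(NULL, cp_names))
  for (j in seq_along(cp_names)) {
    cj <- 2 + which(locus_cols == cp_names[j])
    cp[, j] <- parse_allele(mat[, cj], seq_len(n), rep(cj, n), path)
  }
  genotype_matrix(ind, nuclear = nuc, cp = cp)
}

read_genalex <- function(lines, path) {
  if (length(lines) < 3) stop("malformed header: genalex file ", path,
                              " needs 3 header rows")
  sep <- detect_sep(lines[1])
  rows <- split_fields(lines, sep)
  hdr <- suppressWarnings(as.integer(rows[[1]]))
  if (length(hdr) < 3 || any(is.na(hdr[1:3]))) {
    stop("malformed header in ", path,
         ": row 1 must be n_loci, n_samples, n_pops, pop sizes")
  }
  n_loci <- hdr[1]; n_samples <- hdr[2]; n_pops <- hdr[3]
  pop_sizes <- hdr[3 + seq_len(n_pops)]
  if (any(is.na(pop_sizes)) || sum(pop_sizes) != n_samples) {
    stop("malformed header in ", path,
         ": population sizes do not sum to the sample count")
  }
  colhdr <- rows[[3]]
  nuc_names <- colhdr[2 + 2 * seq_len(n_loci) - 1]
  if (any(is.na(nuc_names)) || any(nuc_names == "")) {
    stop("malformed header in ", path, ": missing nuclear locus names in row 3")
  }
  cp_names <- colhdr[-seq_len(2 + 2 * n_loci)]
  cp_names <- cp_names[cp_names != ""]
  ncol_expected <- 2 + 2 * n_loci + length(cp_names)
  data <- rows[-(1:3)]
  if (length(data) != n_samples) {
    stop("malformed header in ", path, ": header declares ", n_samples,
         " samples but file has ", length(data), " data rows")
  }
  data <- lapply(data, function(r) {
    if (length(r) < ncol_expected) c(r, rep("", ncol_expected - length(r)))
    else r[seq_len(ncol_expected)]
  })
  mat <- if (n_samples) do.call(rbind, data) else
    matrix(character(0), 0, ncol_expected)
  n <- n_samples
  ind <- data.frame(name = mat[, 1], group = mat[, 2],
                    stringsAsFactors = FALSE)
  nuc <- array(NA_integer_, dim = c(n, n_loci, 2),
               dimnames = list(NULL, nuc_names, NULL))
  for (j in seq_len(n_loci)) {
    nuc[, j, 1] <- parse_allele(mat[, 2 * j + 1], seq_len(n) + 3,
                                rep(2 * j + 1, n), path)
    nuc[, j, 2] <- parse_allele(mat[, 2 * j + 2], seq_len(n) + 3,
                                rep(2 * j + 2, n), path)
  }
  cp <- matrix(NA_integer_, n, length(cp_names),
               dimnames = list(NULL, cp_names))
  for (j in seq_along(cp_names)) {
    cp[, j] <- parse_allele(mat[, 2 + 2 * n_loci + j], seq_len(n) + 3,
                            rep(2 + 2 * n_loci + j, n), path)
  }
  # group structure is taken from the Pop column; header totals must agree
  tab <- as.integer(table(ind$group))
  if (n_samples > 0 &&
      (length(tab) != n_pops || !identical(sort(tab), sort(pop_sizes)))) {
    stop("malformed header in ", path,
         ": declared population sizes disagree with the Pop column")
  }
  genotype_matrix(ind, nuclear = nuc, cp = cp)
}

#' Write a genotype table
#'
#' Missing calls are written as `0` in both dialects. The output is readable
#' by [read_genotypes()] into a matrix equal to the input (round trip).
#'
#' @param gm a [genotype_matrix()].
#' @param path output file.
#' @param dialect `"tabular"` or `"genalex"` (see [read_genotypes()]).
#' @param sep field separator for the tabular dialect (`","` default).
#' @param title dataset title written into the genalex header.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(gm, path, dialect = c("tabular", "genalex"),
                            sep = ",", title = "ssrpipe export") {
  dialect <- match.arg(dialect)
  nuc_names <- nuclear_loci(gm)
  cp_names <- cp_loci(gm)
  n <- n_individuals(gm)
  code <- function(x) ifelse(is.na(x), "0", as.character(x))
  nuc_cols <- list()
  for (j in seq_along(nuc_names)) {
    nuc_cols[[2 * j - 1]] <- code(gm$nuclear[, j, 1])
    nuc_cols[[2 * j]] <- code(gm$nuclear[, j, 2])
  }
  cp_cols <- lapply(seq_along(cp_names), function(j) code(gm$cp[, j]))
  body <- c(list(gm$individuals$name, gm$individuals$group),
            nuc_cols, cp_cols)
  body <- lapply(body, function(x) if (length(x)) x else character(0))
  rows <- if (n) do.call(paste, c(body, sep = sep)) else character(0)

  if (dialect == "tabular") {
    header <- paste(c("name", "group",
                      if (length(nuc_names))
                        paste0(rep(nuc_names, each = 2), c("_1", "_2")),
                      cp_names), collapse = sep)
    out <- c(header, rows)
  } else {
    pops <- unique(gm$individuals$group)
    sizes <- as.integer(table(factor(gm$individuals$group, levels = pops)))
    r1 <- paste(c(length(nuc_names), n, length(pops), sizes), collapse = sep)
    r2 <- paste(c(title, "", pops), collapse = sep)
    r3 <- paste(c("Sample", "Pop",
                  if (length(nuc_names)) as.vector(rbind(nuc_names, "")),
                  cp_names), collapse = sep)
    out <- c(r1, r2, r3, rows)
  }
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(out, con)
  invisible(path)
}
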