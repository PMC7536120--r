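#' Read biallelic SNPs from a VCF file
#'
#' Parses a VCF 4.x file into a variant table of biallelic SNPs with per-sample
#' allele dosages, and, when the GT fields are phased (`|` separator), a set of
#' phased haplotypes. Multiallelic records and indels are skipped, not errors:
#' downstream analyses operate on biallelic SNPs only. The number of skipped
#' records of each kind is kept in the `skipped` element.
#'
#' @param path Path to an uncompressed or gzipped VCF file.
#' @param phased_required If `TRUE`, unphased GT separators (`/`) raise an
#'   error instead of silently yielding a table without haplotypes.
#' @return A list of class `variant_table` with elements:
#'   \describe{
#'     \item{variants}{data.frame with `chrom`, `pos` (1-based), `ref`, `alt`.}
#'     \item{dosage}{sites x samples integer matrix of alternate-allele dosages
#'       (0/1/2, `NA` for missing).}
#'     \item{haplotypes}{a [haplotype_set()] when all GT fields are phased,
#'       otherwise `NULL`.}
#'     \item{skipped}{named counts of skipped `multiallelic` and `indel`
#'       records.}
#'   }
#' @export
read_vcf <- function(path, phased_required = FALSE) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  head_lines <- readLines(path, n = 1L)
  if (length(head_lines) == 0L || !grepl("^##fileformat=VCF", head_lines[1]))
    stop("not a VCF 4.x file (missing ##fileformat header): ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  n_rec <- nrow(fix)
  samples <- colnames(v@gt)[-1]
  empty <- function() {
    structure(list(
      variants = data.frame(chrom = character(), pos = integer(),
                            ref = character(), alt = character(),
                            stringsAsFactors = FALSE),
      dosage = matrix(integer(), 0L, length(samples),
                      dimnames = list(NULL, samples)),
      haplotypes = NULL,
      skipped = c(multiallelic = 0L, indel = 0L)
    ), class = "variant_table")
  }
  if (n_rec == 0L) return(empty())

  alt <- fix$ALT
  ref <- fix$REF
  multi <- grepl(",", alt, fixed = TRUE)
  indel <- !multi & (nchar(ref) != 1L | nchar(alt) != 1L | alt == "." |
                       !ref %in% c("A", "C", "G", "T"))
  keep <- !multi & !indel
  skipped <- c(multiallelic = sum(multi), indel = sum(indel))
  if (sum(skipped) > 0L)
    message("read_vcf: skipped ", skipped[["multiallelic"]],
            " multiallelic and ", skipped[["indel"]], " indel/non-SNP records")
  if (!any(keep)) {
    out <- empty()
    out$skipped <- skipped
    return(out)
  }

  gt_raw <- v@gt[keep, -1, drop = FALSE]
  gt <- sub(":.*$", "", gt_raw)
  phased_sep <- grepl("|", gt, fixed = TRUE)
  unphased_sep <- grepl("/", gt, fixed = TRUE)
  if (phased_required && any(unphased_sep))
    stop("phased genotypes required but '/' separators found")

  a1 <- substr(gt, 1L, 1L)
  a2 <- substr(gt, 3L, 3L)
  to_int <- function(x) {
    out <- suppressWarnings(as.integer(x))
    out[!x %in% c("0", "1")] <- NA_integer_
    out
  }
  h1 <- matrix(to_int(a1), nrow = sum(keep))
  h2 <- matrix(to_int(a2), nrow = sum(keep))
  dosage <- h1 + h2
  dimnames(dosage) <- list(NULL, samples)

  haps <- NULL
  if (all(phased_sep | gt %in% c(".", "./.", ".|.")) && any(phased_sep)) {
    allele_mat <- matrix(NA_integer_, nrow = 2L * length(samples),
                         ncol = sum(keep))
    hap_names <- character(2L * length(samples))
    for (s in seq_along(samples)) {
      allele_mat[2L * s - 1L, ] <- h1[, s]
      allele_mat[2L * s, ] <- h2[, s]
      hap_names[2L * s - 1L] <- paste0(samples[s], "_1")
      hap_names[2L * s] <- paste0(samples[s], "_2")
    }
    rownames(allele_mat) <- hap_names
    haps <- haplotype_set(positions = as.integer(fix$POS[keep]),
                          alleles = allele_mat,
                          samples = rep(samples, each = 2L))
  } else if (phased_required) {
    stop("phased genotypes required but records are not uniformly phased")
  }

  structure(list(
    variants = data.frame(chrom = fix$CHROM[keep],
                          pos = as.integer(fix$POS[keep]),
                          ref = ref[keep], alt = alt[keep],
                          stringsAsFactors = FALSE),
    dosage = dosage,
    haplotypes = haps,
    skipped = skipped
  ), class = "variant_table")
}

#' Construct a phased haplotype set
#'
#' Container for phased binary haplotypes: rows are haplotypes, columns are
#' sites; 0 is the ancestral (reference) allele and 1 the derived allele.
#'
#' @param positions Integer vector of 1-based site positions, strictly
#'   increasing.
#' @param alleles Haplotype x site matrix with entries in \{0, 1\} (`NA`
#'   allowed for missing).
#' @param samples Optional sample-of-origin for each haplotype row.
#' @return An object of class `haplotype_set`.
#' @export
haplotype_set <- function(positions, alleles, samples = NULL) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  if (length(positions) != ncol(alleles))
    stop("length(positions) must equal ncol(alleles)")
  if (is.unsorted(positions, strictly = TRUE))
    stop("positions must be strictly increasing")
  bad <- !is.na(alleles) & !alleles %in% c(0L, 1L)
  if (any(bad)) stop("haplotype alleles must be 0, 1 or NA")
  structure(list(positions = as.numeric(positions), alleles = alleles,
                 samples = samples), class = "haplotype_set")
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat("haplotype_set:", nrow(x$alleles), "haplotypes x",
      ncol(x$alleles), "sites\n")
  invisible(x)
}

#' @export
print.variant_table <- function(x, ...) {
  cat("variant_table:", nrow(x$variants), "biallelic SNPs x",
      ncol(x$dosage), "samples",
      if (!is.null(x$haplotypes)) "(phased)" else "", "\n")
  invisible(x)
}

#' Write a variant table (optionally with phased haplotypes) to VCF
#'
#' Minimal deterministic VCF 4.2 writer for biallelic SNPs; emits GT fields
#' only. Used to round-trip synthetic data through standard formats.
#'
#' @param vt A `variant_table` (see [read_vcf()]); if its `haplotypes` element
#'   is present, phased `a|b` genotypes are written, else unphased dosages.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(vt, path) {
  samples <- colnames(vt$dosage)
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  n <- nrow(vt$variants)
  body <- character(n)
  for (i in seq_len(n)) {
    if (!is.null(vt$haplotypes)) {
      h <- vt$haplotypes$alleles[, i]
      gt <- paste(ifelse(is.na(h[c(TRUE, FALSE)]), ".", h[c(TRUE, FALSE)]),
                  ifelse(is.na(h[c(FALSE, TRUE)]), ".", h[c(FALSE, TRUE)]),
                  sep = "|")
    } else {
      d <- vt$dosage[i, ]
      gt <- c("0/0", "0/1", "1/1")[d + 1L]
      gt[is.na(d)] <- "./."
    }
    body[i] <- paste(c(vt$variants$chrom[i], vt$variants$pos[i], ".",
                       vt$variants$ref[i], vt$variants$alt[i], ".", "PASS",
                       ".", "GT", gt), collapse = "\t")
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Sample metadata with subpopulation membership
#'
#' Holds per-sample subpopulation labels and fastStructure-style maximum
#' membership coefficients; a sample with `qi < 0.7` is considered admixed
#' and relabelled `"admixed"`, the convention used to restrict PAV and
#' enrichment analyses to non-admixed individuals.
#'
#' @param id Sample identifiers.
#' @param subpop Assigned subpopulation labels.
#' @param qi Maximum membership coefficients in \[0, 1\] (default 1, i.e.
#'   fully assigned).
#' @param admixed_below Threshold under which a sample is admixed.
#' @param lat,lon Optional coordinates.
#' @return data.frame of class `sample_metadata` with an `admixed` column;
#'   admixed samples carry the label `"admixed"`.
#' @export
sample_metadata <- function(id, subpop, qi = 1, admixed_below = 0.7,
                            lat = NA_real_, lon = NA_real_) {
  qi <- rep_len(qi, length(id))
  if (any(qi < 0 | qi > 1)) stop("qi must be in [0, 1]")
  admixed <- qi < admixed_below
  subpop <- as.character(subpop)
  subpop[admixed] <- "admixed"
  structure(data.frame(id = as.character(id), subpop = subpop, qi = qi,
                       admixed = admixed, lat = lat, lon = lon,
                       stringsAsFactors = FALSE),
            class = c("sample_metadata", "data.frame"))
}

#' Read a gene presence/absence matrix from TSV
#'
#' Expects a tab-delimited file whose first column holds gene identifiers and
#' remaining columns hold 0/1 presence calls, one column per library.
#'
#' @param path Path to the TSV file.
#' @return A genes x libraries integer matrix of class `pav_matrix`.
#' @export
read_pav_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("PAV matrix needs a gene column plus >=1 library")
  genes <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  bad <- which(!(m %in% c(0, 1)) | is.na(m))
  if (length(bad)) {
    i <- ((bad[1] - 1L) %% nrow(m)) + 1L
    j <- ((bad[1] - 1L) %/% nrow(m)) + 1L
    stop(sprintf("non-binary PAV cell at gene '%s', library '%s': '%s'",
                 genes[i], colnames(m)[j], as.character(m[i, j])))
  }
  storage.mode(m) <- "integer"
  rownames(m) <- genes
  pav_matrix(m)
}

#' Construct a PAV matrix object
#'
#' @param m Genes x libraries matrix with entries in \{0, 1\}.
#' @return Integer matrix of class `pav_matrix`.
#' @export
pav_matrix <- function(m) {
  m <- as.matrix(m)
  if (any(!(m %in% c(0, 1)) | is.na(m))) stop("PAV entries must be 0 or 1")
  storage.mode(m) <- "integer"
  class(m) <- c("pav_matrix", class(m))
  m
}

#' Per-gene occupancy of a PAV matrix
#'
#' Occupancy is the fraction of libraries in which a gene is called present.
#'
#' @param pav A `pav_matrix` (genes x libraries).
#' @return Numeric vector of per-gene occupancies in \[0, 1\].
#' @export
occupancy <- function(pav) rowMeans(unclass(pav))

#' Write a PAV matrix to TSV
#'
#' @param pav A `pav_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pav_matrix <- function(pav, path) {
  df <- data.frame(gene = rownames(pav), unclass(pav), check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_table(df, path)
}

#' Read FASTA sequences as a named character vector
#'
#' Sequences are uppercased; IUPAC ambiguity letters are preserved. Duplicate
#' record identifiers are an error.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids))
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  out <- toupper(as.character(ss))
  names(out) <- ids
  out
}

#' Write named sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line width for wrapping (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (is.null(names(seqs)) || any(names(seqs) == ""))
    stop("all sequences must be named")
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Write a results table as deterministic TSV
#'
#' Tab-delimited, header row, no quoting, no row names; column order is taken
#' from the data frame, so repeated writes of equal input are byte-identical.
#'
#' @param df A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

#' Read a table written by [write_table()]
#'
#' @param path Path to the TSV file.
#' @return A data frame.
#' @export
read_table <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}
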