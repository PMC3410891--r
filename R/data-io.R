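#' Construct a genotype matrix for a panel of inbred lines
#'
#' Container for biallelic homozygous genotype calls. Calls count copies of
#' \code{allele_b}, so the only admissible values are 0 (homozygous
#' \code{allele_a}), 2 (homozygous \code{allele_b}) and \code{NA}. Heterozygous
#' calls never enter the container; they are resolved at read time (see
#' \code{\link{read_genotypes}}).
#'
#' @param calls integer matrix, markers in rows and accessions in columns,
#'   values in \{0, 2, NA\}.
#' @param map data frame with columns \code{marker_id}, \code{chrom},
#'   \code{pos} (1-based), \code{allele_a}, \code{allele_b}; one row per row
#'   of \code{calls}.
#' @param accession_ids character vector of line identifiers; defaults to
#'   \code{colnames(calls)}.
#' @return An object of class \code{"geno_matrix"}: a list with elements
#'   \code{calls} (dimnamed matrix) and \code{map}.
#' @export
geno_matrix <- function(calls, map, accession_ids = colnames(calls)) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (is.null(accession_ids)) {
    stop("accession ids are required (column names or `accession_ids`)")
  }
  req <- c("marker_id", "chrom", "pos", "allele_a", "allele_b")
  if (!all(req %in% names(map))) {
    stop("map must have columns: ", paste(req, collapse = ", "))
  }
  map <- as.data.frame(map)[, req]
  if (nrow(map) != nrow(calls)) stop("map and calls disagree on marker count")
  if (anyDuplicated(map$marker_id)) {
    stop("duplicate marker id: ", map$marker_id[duplicated(map$marker_id)][1L])
  }
  if (anyDuplicated(accession_ids)) stop("duplicate accession ids")
  if (any(map$pos <= 0L)) stop("positions must be strictly positive (1-based)")
  bad <- calls[!is.na(calls)]
  if (!all(bad %in% c(0L, 2L))) {
    stop("calls must be 0, 2 or NA (copies of allele_b in inbred lines)")
  }
  dimnames(calls) <- list(map$marker_id, accession_ids)
  structure(list(calls = calls, map = map), class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("Genotype matrix: %d markers x %d accessions (inbred, calls in {0,2,NA})\n",
              nrow(x$calls), ncol(x$calls)))
  cat(sprintf("  chromosomes: %s\n", paste(unique(x$map$chrom), collapse = ", ")))
  cat(sprintf("  missing calls: %.2f%%\n", 100 * mean(is.na(x$calls))))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$calls)

#' Read genotypes from TSV or VCF
#'
#' The TSV dialect has header
#' \code{marker_id chrom pos allele_a allele_b <acc1> <acc2> ...} with call
#' cells in \{0, 2, NA\}. VCF input (4.x, biallelic SNPs, GT field) is parsed
#' with \pkg{vcfR}; calls are coded as copies of ALT (\code{allele_b}).
#'
#' @param path file path.
#' @param format \code{"tsv"} or \code{"vcf"}.
#' @param het_policy how to treat heterozygous VCF calls: \code{"missing"}
#'   (default; the cell becomes NA — residual heterozygosity in inbred panels
#'   is treated as noise) or \code{"drop"} (markers carrying any heterozygous
#'   call are removed entirely).
#' @return A \code{\link{geno_matrix}}.
#' @export
read_genotypes <- function(path, format = c("tsv", "vcf"),
                           het_policy = c("missing", "drop")) {
  format <- match.arg(format)
  het_policy <- match.arg(het_policy)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "tsv") read_genotypes_tsv(path) else read_genotypes_vcf(path, het_policy)
}

read_genotypes_tsv <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L) stop("genotype TSV needs a header and >= 1 marker row")
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  fixed <- c("marker_id", "chrom", "pos", "allele_a", "allele_b")
  if (length(header) < 6L || !identical(header[1:5], fixed)) {
    stop("genotype TSV header must start with: ", paste(fixed, collapse = " "))
  }
  acc <- header[-(1:5)]
  n <- length(lines) - 1L
  calls <- matrix(NA_integer_, n, length(acc))
  map <- data.frame(marker_id = character(n), chrom = character(n),
                    pos = integer(n), allele_a = character(n),
                    allele_b = character(n), stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    f <- strsplit(lines[i + 1L], "\t", fixed = TRUE)[[1L]]
    if (length(f) != length(header)) {
      stop(sprintf("parse error at line %d of %s: expected %d fields, got %d",
                   i + 1L, path, length(header), length(f)))
    }
    pos <- suppressWarnings(as.integer(f[3L]))
    if (is.na(pos)) stop(sprintf("parse error at line %d of %s: bad position '%s'",
                                 i + 1L, path, f[3L]))
    map[i, ] <- list(f[1L], f[2L], pos, f[4L], f[5L])
    cells <- f[-(1:5)]
    v <- suppressWarnings(as.integer(cells))
    ok <- cells == "NA" | (!is.na(v) & v %in% c(0L, 2L))
    if (!all(ok)) {
      stop(sprintf("parse error at line %d of %s: call '%s' not in {0, 2, NA}",
                   i + 1L, path, cells[!ok][1L]))
    }
    calls[i, ] <- v
  }
  geno_matrix(calls, map, acc)
}

read_genotypes_vcf <- function(path, het_policy) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  if (any(grepl(",", alt, fixed = TRUE))) {
    stop("multiallelic sites rejected: ", fix[grepl(",", alt, fixed = TRUE), "ID"][1L])
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1, dimnames = list(NULL, names(gt)))
  core <- sub(":.*$", "", gt)
  code <- matrix(NA_integer_, nrow(core), ncol(core))
  code[core %in% c("0/0", "0|0", "0")] <- 0L
  code[core %in% c("1/1", "1|1", "1")] <- 2L
  het <- core %in% c("0/1", "1/0", "0|1", "1|0")
  ids <- fix[, "ID"]
  miss_id <- is.na(ids) | ids == "."
  ids[miss_id] <- paste0(fix[miss_id, "CHROM"], "_", fix[miss_id, "POS"])
  keep <- rep(TRUE, nrow(code))
  if (het_policy == "drop") keep <- !apply(matrix(het, nrow(core)), 1L, any)
  # het_policy == "missing": heterozygous cells stay NA from initialisation
  map <- data.frame(marker_id = ids, chrom = fix[, "CHROM"],
                    pos = as.integer(fix[, "POS"]),
                    allele_a = fix[, "REF"], allele_b = alt,
                    stringsAsFactors = FALSE)
  geno_matrix(code[keep, , drop = FALSE], map[keep, , drop = FALSE], colnames(gt))
}

#' Write genotypes in the package TSV dialect
#'
#' Inverse of \code{read_genotypes(format = "tsv")}; round-trips exactly.
#'
#' @param G a \code{\link{geno_matrix}}.
#' @param path output path.
#' @export
write_genotypes <- function(G, path) {
  stopifnot(inherits(G, "geno_matrix"))
  header <- paste(c("marker_id", "chrom", "pos", "allele_a", "allele_b",
                    colnames(G$calls)), collapse = "\t")
  cells <- G$calls
  cells[is.na(cells)] <- NA
  rows <- vapply(seq_len(nrow(cells)), function(i) {
    paste(c(G$map$marker_id[i], G$map$chrom[i], G$map$pos[i],
            G$map$allele_a[i], G$map$allele_b[i],
            ifelse(is.na(cells[i, ]), "NA", cells[i, ])), collapse = "\t")
  }, character(1L))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a phenotype table
#'
#' Header \code{accession_id <trait1> <trait2> ...}; NA marks missing values.
#'
#' @param path TSV file path.
#' @return data frame with character column \code{accession_id} and one
#'   numeric column per trait.
#' @export
read_phenotypes <- function(path) {
  p <- utils::read.table(path, header = TRUE, sep = "\t",
                         colClasses = NA, check.names = FALSE,
                         stringsAsFactors = FALSE)
  if (names(p)[1L] != "accession_id") stop("first phenotype column must be accession_id")
  p$accession_id <- as.character(p$accession_id)
  if (anyDuplicated(p$accession_id)) stop("duplicate accession ids in phenotype table")
  if (ncol(p) < 2L) stop("phenotype table has no trait columns")
  for (j in 2:ncol(p)) {
    p[[j]] <- as.numeric(p[[j]])
    if (all(is.na(p[[j]]))) stop("trait '", names(p)[j], "' has no non-missing values")
  }
  p
}

#' Write a phenotype table
#' @param P phenotype data frame (see \code{\link{read_phenotypes}}).
#' @param path output path.
#' @export
write_phenotypes <- function(P, path) {
  utils::write.table(P, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read candidate-gene intervals (BED-like)
#'
#' Columns \code{chrom start end gene_id} with BED 0-based half-open
#' coordinates; converted on read to 1-based inclusive, matching marker
#' positions.
#'
#' @param path TSV file path (no header).
#' @return data frame with \code{chrom}, \code{start}, \code{end} (1-based
#'   inclusive) and \code{gene_id}.
#' @export
read_gene_intervals <- function(path) {
  g <- utils::read.table(path, header = FALSE, sep = "\t",
                         col.names = c("chrom", "start", "end", "gene_id"),
                         stringsAsFactors = FALSE)
  if (any(g$end <= g$start)) stop("empty interval (end <= start) in ", path)
  g$start <- g$start + 1L  # BED half-open -> 1-based inclusive
  g$chrom <- as.character(g$chrom)
  g$gene_id <- as.character(g$gene_id)
  g
}

#' Accessions usable for one trait
#'
#' Intersects the genotype panel with the phenotyped lines and drops lines
#' missing the trait value. Order follows the genotype matrix, so the result
#' does not depend on phenotype row order.
#'
#' @param G a \code{\link{geno_matrix}}.
#' @param P phenotype data frame.
#' @param trait trait (column) name in \code{P}.
#' @return character vector of accession ids.
#' @export
align_complete_cases <- function(G, P, trait) {
  stopifnot(inherits(G, "geno_matrix"))
  if (!trait %in% names(P)) stop("trait '", trait, "' not in phenotype table")
  have <- P$accession_id[!is.na(P[[trait]])]
  keep <- colnames(G$calls)[colnames(G$calls) %in% have]
  if (length(keep) == 0L) {
    stop("no accession is both genotyped and phenotyped for '", trait, "'")
  }
  keep
}

#' Per-marker genotype grouping
#'
#' Splits a subset of accessions by their call at one marker. For inbred
#' biallelic data at most two groups exist (the two homozygotes).
#'
#' @param G a \code{\link{geno_matrix}}.
#' @param marker marker id.
#' @param accessions accession ids to use; default all.
#' @return An object of class \code{"geno_groups"}: list with \code{calls}
#'   (named call vector, NA for missing), \code{n_low}/\code{n_high} (counts
#'   of calls 0 and 2), \code{n} (named count vector over non-empty groups),
#'   \code{K} (number of non-empty groups) and \code{N} (non-missing total).
#' @export
genotype_groups <- function(G, marker, accessions = colnames(G$calls)) {
  stopifnot(inherits(G, "geno_matrix"))
  if (!marker %in% rownames(G$calls)) stop("no such marker: ", marker)
  calls <- G$calls[marker, accessions]
  n_low <- sum(calls == 0L, na.rm = TRUE)
  n_high <- sum(calls == 2L, na.rm = TRUE)
  n <- c(`0` = n_low, `2` = n_high)
  n <- n[n > 0L]
  structure(list(calls = calls, n_low = n_low, n_high = n_high,
                 n = n, K = length(n), N = n_low + n_high),
            class = "geno_groups")
}

# internal: build geno_groups straight from a call vector (scan hot path)
groups_from_calls <- function(calls) {
  n_low <- sum(calls == 0L, na.rm = TRUE)
  n_high <- sum(calls == 2L, na.rm = TRUE)
  n <- c(`0` = n_low, `2` = n_high)
  n <- n[n > 0L]
  structure(list(calls = calls, n_low = n_low, n_high = n_high,
                 n = n, K = length(n), N = n_low + n_high),
            class = "geno_groups")
}

#' Minor-allele frequency of a marker
#'
#' For fully homozygous lines the minor genotype frequency equals the minor
#' allele frequency, so the MAF is \code{min(n_low, n_high) / N}. Monomorphic
#' markers (K = 1) have MAF 0.
#'
#' @param groups a \code{\link{genotype_groups}} result.
#' @return frequency in [0, 0.5].
#' @export
maf <- function(groups) {
  stopifnot(inherits(groups, "geno_groups"))
  if (groups$N == 0L) stop("no non-missing calls: MAF undefined")
  if (groups$K < 2L) return(0)
  min(groups$n_low, groups$n_high) / groups$N
}
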