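# shared in-code fixtures for the test suite

# small genotype matrix built directly (no files)
tiny_geno <- function() {
  calls <- rbind(c(0L, 0L, 2L, 2L, 2L),
                 c(0L, 2L, 0L, 2L, NA),
                 c(0L, 0L, 0L, 0L, 0L))
  map <- data.frame(marker_id = c("m1", "m2", "m3"), chrom = c("1", "1", "2"),
                    pos = c(100L, 200L, 50L), allele_a = "A", allele_b = "G",
                    stringsAsFactors = FALSE)
  geno_matrix(calls, map, paste0("acc", 1:5))
}

tiny_pheno <- function() {
  data.frame(accession_id = paste0("acc", 1:5),
             t1 = c(1.2, 0.8, 3.1, 2.9, 3.3),
             t2 = c(NA, 1.0, 2.0, 3.0, 4.0),
             stringsAsFactors = FALSE)
}

# geno_groups straight from a call vector
groups_of <- function(calls) {
  names(calls) <- paste0("acc", seq_along(calls))
  vargwas:::groups_from_calls(calls)
}

# balanced two-group split helper for test statistics
split_groups <- function(n0, n1) groups_of(c(rep(0L, n0), rep(2L, n1)))

# brute-force Brown-Forsythe oracle: direct formula arithmetic on z,
# independent of the package implementation
bf_oracle <- function(y, g) {
  z <- unlist(lapply(split(y, g), function(v) abs(v - stats::median(v))))
  gg <- unlist(lapply(split(g, g), identity))
  K <- length(unique(gg)); N <- length(z)
  zbar <- mean(z)
  num <- sum(tapply(z, gg, function(v) length(v) * (mean(v) - zbar)^2)) / (K - 1)
  den <- sum(unlist(lapply(split(z, gg), function(v) (v - mean(v))^2))) / (N - K)
  num / den
}

# deterministic RNG wrapper for property-style loops
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  force(code)
}

write_tiny_vcf <- function(path, alt = "G", gt2 = "1/1") {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=1>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "s1", "s2", "s3"), collapse = "\t"),
    paste(c("1", "100", "v1", "A", alt, ".", "PASS", ".", "GT",
            "0/0", gt2, "1/1"), collapse = "\t"),
    paste(c("1", "200", "v2", "C", "T", ".", "PASS", ".", "GT",
            "1/1", "0/0", "./."), collapse = "\t")), path)
  path
}
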