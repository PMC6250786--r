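## Shared helpers: deterministic founders/hybrids and brute-force oracles
## kept independent of the package's own segment arithmetic.

## An F1 hermaphrodite (heterozygous genome-wide, maternal mitotype) built
## from a founder cross; caller controls the RNG seed.
f1_herm <- function(male_pop = "AF16", herm_pop = "HK104",
                    genome = default_genome_spec()) {
  off <- cross(founder(male_pop, "male", genome),
               founder(herm_pop, "hermaphrodite", genome), 30)
  sexes <- vapply(off, function(i) i$sex, "")
  off[[which(sexes == "hermaphrodite")[1L]]]
}

f1_male <- function(male_pop = "AF16", herm_pop = "HK104",
                    genome = default_genome_spec()) {
  off <- cross(founder(male_pop, "male", genome),
               founder(herm_pop, "hermaphrodite", genome), 30)
  sexes <- vapply(off, function(i) i$sex, "")
  off[[which(sexes == "male")[1L]]]
}

## Ancestry lookup by explicit segment scan (no findInterval).
ancestry_oracle <- function(h, pos) {
  for (i in seq_along(h$a)) {
    if (pos >= h$b[i] && pos < h$b[i + 1L]) return(h$a[i])
  }
  stop("position outside haplotype")
}

## Random (canonical) haplotype for property tests.
random_hap <- function(L = 1e6, k = 5) {
  cuts <- sort(sample.int(L - 1, k))
  haplotype(c(0, cuts, L), sample(c("AF16", "HK104"), k + 1, replace = TRUE))
}

## Small all-heterozygous table for counting checks.
all_het_table <- function(n = 4, marker = "cb51757") {
  df <- data.frame(line_id = sprintf("L%02d", seq_len(n)), design = "F2RIL",
                   male_pop = "AF16", herm_pop = "HK104", mitotype = "HK104",
                   stringsAsFactors = FALSE)
  df[[marker]] <- rep("AH", n)
  genotype_table(df)
}
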