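# In-code fixtures shared across test files.

toy_map <- function() {
  marker_map(data.frame(
    marker = c("P1", "P2", "D1"),
    side = c("proximal", "proximal", "distal"),
    dist_cM = c(1, 5, 2),
    repeat_unit = 2,
    mu = 5.6e-4))
}

# build a haplotype set from allele matrices (rows = chromosomes)
make_set <- function(map, carriers, controls = NULL,
                     carrier_independent = TRUE) {
  stopifnot(ncol(carriers) == nrow(map))
  colnames(carriers) <- map$marker
  n_car <- nrow(carriers)
  n_ctl <- if (is.null(controls)) 0 else nrow(controls)
  if (n_ctl > 0) colnames(controls) <- map$marker
  meta <- data.frame(
    chrom_id = sprintf("c%03d", seq_len(n_car + n_ctl)),
    family_id = sprintf("f%03d", seq_len(n_car + n_ctl)),
    group = c(rep("carrier", n_car), rep("control", n_ctl)),
    independent = c(rep(carrier_independent, length.out = n_car),
                    rep(TRUE, n_ctl)),
    stringsAsFactors = FALSE)
  alleles <- as.data.frame(rbind(carriers, if (n_ctl > 0) controls))
  haplotype_set(map, cbind(meta, alleles))
}

# randomized set for round-trip properties (may contain missing alleles)
random_set <- function(seed, n = 12, p_missing = 0.1) {
  set.seed(seed)
  map <- toy_map()
  m <- matrix(sample(5:30, n * nrow(map), replace = TRUE), nrow = n)
  m[stats::runif(length(m)) < p_missing] <- NA
  groups <- sample(c("carrier", "control"), n, replace = TRUE)
  groups[1] <- "carrier"  # keep >= 1 carrier
  meta <- data.frame(chrom_id = sprintf("r%03d", seq_len(n)),
                     family_id = sprintf("f%02d", sample(1:4, n, TRUE)),
                     group = groups,
                     independent = sample(c(TRUE, FALSE), n, TRUE),
                     stringsAsFactors = FALSE)
  alleles <- as.data.frame(m)
  names(alleles) <- map$marker
  haplotype_set(map, cbind(meta, alleles))
}
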