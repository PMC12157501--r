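# Shared fixtures built in code at test time.

# Small simulation config for fast end-to-end exercises.
small_cfg <- function(seed = 11L, classes = SIM_CLASSES_ALL, n = 2L,
                      reads_per_arm = 400L) {
  sim_config(seed = seed, n_loci_per_class = n, classes = classes,
             reads_per_arm = reads_per_arm)
}

SIM_CLASSES_ALL <- c("canonical", "mirtron_like", "polIII_noncanonical",
                     "mp_dicer_independent", "piRNA_like", "siRNA26G_like")

# all-zero planted-lfc matrix with the generator's dimnames
null_lfc <- function() {
  matrix(0, length(SIM_CLASSES_ALL), 4,
         dimnames = list(SIM_CLASSES_ALL,
                         c("control", "MP_depleted", "Dicer_depleted",
                           "PolIII_depleted")))
}

# map generator truth classes to expected classifier labels
expected_label <- function(class) {
  c(canonical = "canonical", mirtron_like = "mirtron_like",
    polIII_noncanonical = "polIII_noncanonical",
    mp_dicer_independent = "mp_dicer_independent",
    piRNA_like = "misannotated_piRNA",
    siRNA26G_like = "misannotated_26G")[class]
}

# A hand-built two-locus genome for tailing tests: both arms of locus A,
# plus locus B whose 5p arm sequence is identical to A's 5p arm
# (paralogous arms -> fractional assignment).
manual_genome <- function() {
  arm5 <- "ACGTACGGTTCAGCTAAGCTCG"                      # 22 nt
  arm3 <- "TTGACCGGATACGATCCAGGTC"                      # 22 nt
  loop <- "GTGTGT"
  pre <- paste0(arm5, loop, arm3)
  flank_l <- strrep("CGCATGCA", 15)                     # 120 nt
  flank_r <- paste0("G", strrep("CATG", 20))            # non-A after arm end
  contigA <- paste0(flank_l, pre, flank_r)
  preB <- paste0(arm5, loop, revcomp(arm5))   # perfect 22-pair stem
  contigB <- paste0(flank_l, preB, flank_r)
  genome <- c(ctgA = contigA, ctgB = contigB)
  loci <- loci_frame(data.frame(
    locus_id = c("locA", "locB"), contig_id = c("ctgA", "ctgB"),
    strand = "+", pre_start = 120L, pre_end = 120L + nchar(pre),
    arm5p_start = 120L, arm5p_end = 142L,
    arm3p_start = 148L, arm3p_end = 170L,
    stringsAsFactors = FALSE))
  list(genome = genome, loci = loci, arm5 = arm5, arm3 = arm3)
}
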