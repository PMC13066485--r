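# small deterministic builders used across test files

# dataset from explicit assay vectors, demographics defaulted
make_dataset <- function(clia, lcms, sex = NULL, age = NULL,
                         provenance = "fixture") {
  n <- length(clia)
  if (is.null(sex)) sex <- rep(c("female", "male"), length.out = n)
  if (is.null(age)) age <- seq(25, 70, length.out = n)
  paired_dataset(sprintf("fx%03d", seq_len(n)), age, sex, clia, lcms,
                 provenance = provenance)
}

# cohort reproducing the 20 ng/mL cross-tab of the reference study:
# 60 both-above, 5 CLIA>=20 & LCMS<20, 7 CLIA<20 & LCMS>=20, 66 both-below,
# with every value far from 30 so the 30 ng/mL cut adds no discordance
make_crosstab_cohort <- function() {
  clia <- c(rep(22, 60), rep(22, 5), rep(15, 7), rep(15, 66))
  lcms <- c(rep(24, 60), rep(15, 5), rep(22, 7), rep(14, 66))
  make_dataset(clia, lcms)
}

# three well-separated 2-D points (hard-clustering limit fixture)
distant_points <- function() {
  rbind(c(0, 0), c(100, 0), c(0, 100))
}

# 30-point 2-D three-cluster fixture for the FCM reference-oracle test
fcm_fixture <- function() {
  withr::with_seed(42, {
    rbind(matrix(stats::rnorm(20, 0), 10, 2),
          matrix(stats::rnorm(20, 4), 10, 2),
          matrix(stats::rnorm(20, c(0, 8)), 10, 2))
  })
}
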