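# Study-shaped synthetic scenario: two cohorts (20 cases / 30 controls),
# two body sites, Lactobacillus-dominated vs diverse state types, planted
# basis correlations, contaminants in the low-biomass site. Parameter
# choices are documented in the methods vignette and are not tuning knobs.

VAGINAL_GENERA <- c(
  "Lactobacillus", "Gardnerella", "Bifidobacterium", "Prevotella",
  "Atopobium", "Anaerococcus", "Aerococcus", "Streptococcus",
  "Staphylococcus", "Escherichia/Shigella", "Bacteroides", "Actinomyces",
  "Sneathia", "Ureaplasma", "Campylobacter", "Dialister", "Varibaculum",
  "Finegoldia", "Peptoniphilus", "Corynebacterium")

BLADDER_EXTRA_GENERA <- c(
  "Faecalibacterium", "Blautia", "Akkermansia", "Roseburia", "Ruminococcus",
  "Agathobacter", "Lachnospira", "Alistipes", "Enterococcus", "Veillonella",
  "Actinotignum", "Subdoligranulum", "Anaerostipes", "Dorea", "Fusobacterium",
  "Salmonella", "Peptostreptococcus", "Butyrivibrio", "Oscillibacter",
  "Flavonifractor")

PHYLA <- c("Firmicutes", "Actinobacteria", "Bacteroidetes", "Proteobacteria",
           "Fusobacteria", "Tenericutes", "Epsilonbacteraeota",
           "Verrucomicrobia")

#' Simulate the study-shaped paired-site scenario
#'
#' Generates a complete synthetic study: `n_case + n_control` participants,
#' each contributing a vaginal and a bladder sample; genus-level
#' compositional counts with planted basis correlations (a few pairs at
#' rho = 0.6 per site), Lactobacillus-dominated vs diverse community state
#' types, random bifurcating trees per site, sample metadata (cohort, age,
#' BMI, menopause, estrogen use, vaginal product use, DNA concentration)
#' and, in the low-biomass bladder site, contaminant taxa whose frequency
#' scales inversely with DNA concentration.
#'
#' @param seed integer seed; the whole scenario is deterministic given it.
#' @param n_case,n_control cohort sizes (defaults 20 / 30).
#' @param n_taxa_vaginal,n_taxa_bladder genus counts per site
#'   (defaults 66 / 131, the study's post-filter genus counts).
#' @param n_contaminants contaminant taxa spiked into the bladder table
#'   (default 3).
#' @return list with `vaginal`, `bladder` (count tables), `metadata`
#'   (per-sample data.frame), `tree_vaginal`, `tree_bladder`, `phylum`
#'   (genus -> phylum map covering both sites) and `truth`.
#' @export
simulate_study <- function(seed = 1, n_case = 20, n_control = 30,
                           n_taxa_vaginal = 66, n_taxa_bladder = 131,
                           n_contaminants = 3) {
  n <- n_case + n_control
  pad <- function(base, k, stem) {
    if (k <= length(base)) base[seq_len(k)]
    else c(base, sprintf("%s%02d", stem, seq_len(k - length(base))))
  }
  vag_taxa <- pad(VAGINAL_GENERA, n_taxa_vaginal, "VagGenus")
  # most vaginal genera are also found in the bladder pool (cf. shared-set
  # sizes implied by published overlap percentages)
  shared_extra <- vag_taxa[seq(2, min(41, length(vag_taxa)))]
  n_only <- max(n_taxa_bladder - length(shared_extra) - 1, 3)
  blad_taxa <- c("Lactobacillus", shared_extra,
                 pad(BLADDER_EXTRA_GENERA, n_only, "BladGenus"))
  with_seed_if(seed, {
    cohort <- rep(c("case", "control"), c(n_case, n_control))
    participant <- sprintf("P%03d", seq_len(n))
    # vaginal state types: product users lean Lactobacillus-dominated
    vaginal_product <- runif(n) < 0.32
    p_dom <- ifelse(vaginal_product, 0.85, 0.45)
    state_vag <- ifelse(runif(n) < p_dom, "dominated", "diverse")
    menopause <- runif(n) < ifelse(cohort == "case", 0.85, 0.70)
    state_blad <- ifelse(runif(n) < ifelse(menopause, 0.30, 0.75),
                         "dominated", "diverse")
    age <- round(rnorm(n, ifelse(cohort == "case", 64.2, 57.9), 10.4), 1)
    bmi <- round(rlnorm(n, log(ifelse(cohort == "case", 29.3, 25.4)), 0.15), 1)
    estrogen <- runif(n) < ifelse(cohort == "case", 0.45, 0.23)
    conc_vag <- rlnorm(n, log(20), 0.8)       # ng/uL; high-biomass site
    conc_blad <- rlnorm(n, log(0.8), 1.0)     # low biomass, wide range

    vag <- simulate_site(vag_taxa, state_vag, dominant = "Lactobacillus",
                         depth_mean = 45000, depth_sdlog = 0.3,
                         n_pairs = 4, participant = participant,
                         site = "vaginal")
    blad <- simulate_site(blad_taxa, state_blad, dominant = "Lactobacillus",
                          depth_mean = 20000, depth_sdlog = 0.9,
                          n_pairs = 6, participant = participant,
                          site = "bladder")
    spiked <- spike_contaminants(blad$counts, setNames(conc_blad, rownames(blad$counts)),
                                 n_contaminants = n_contaminants,
                                 strength = 0.03, noise_sdlog = 0.25)
    tree_vag <- simulate_tree(colnames(vag$counts))
    tree_blad <- simulate_tree(colnames(spiked$counts))
    all_taxa <- unique(c(colnames(vag$counts), colnames(spiked$counts)))
    phylum <- setNames(PHYLA[1 + (seq_along(all_taxa) %% length(PHYLA))], all_taxa)
    phylum[c("Lactobacillus", "Streptococcus", "Staphylococcus", "Aerococcus",
             "Anaerococcus", "Dialister", "Finegoldia", "Peptoniphilus")] <- "Firmicutes"
    phylum[c("Gardnerella", "Bifidobacterium", "Atopobium", "Actinomyces",
             "Varibaculum", "Corynebacterium")] <- "Actinobacteria"
    phylum[c("Prevotella", "Bacteroides")] <- "Bacteroidetes"
    phylum[c("Escherichia/Shigella")] <- "Proteobacteria"
    metadata <- data.frame(
      sample_id = c(rownames(vag$counts), rownames(spiked$counts)),
      participant = rep(participant, 2),
      cohort = rep(cohort, 2),
      site = rep(c("vaginal", "bladder"), each = n),
      age = rep(age, 2), bmi = rep(bmi, 2),
      menopause = rep(menopause, 2),
      estrogen_use = rep(estrogen, 2),
      vaginal_product_use = rep(vaginal_product, 2),
      dna_concentration = c(conc_vag, conc_blad),
      stringsAsFactors = FALSE)
    rownames(metadata) <- metadata$sample_id
    list(vaginal = vag$counts, bladder = spiked$counts,
         metadata = metadata,
         tree_vaginal = tree_vag, tree_bladder = tree_blad,
         phylum = phylum,
         truth = list(seed = seed,
                      state_vaginal = setNames(state_vag, rownames(vag$counts)),
                      state_bladder = setNames(state_blad, rownames(spiked$counts)),
                      planted_pairs_vaginal = vag$pairs,
                      planted_pairs_bladder = blad$pairs,
                      contaminant_flags = spiked$truth$contaminant_flags))
  })
}

# One site's table: correlated log-normal basis with state-type mean shifts.
# Uses the caller's RNG stream.
simulate_site <- function(taxa, state, dominant, depth_mean, depth_sdlog,
                          n_pairs, participant, site) {
  d <- length(taxa)
  n <- length(state)
  corr <- diag(d)
  free <- setdiff(seq_len(d), match(dominant, taxa))
  pairs <- matrix(sample(free, 2 * n_pairs), ncol = 2)
  for (r in seq_len(n_pairs)) corr[pairs[r, 1], pairs[r, 2]] <-
      corr[pairs[r, 2], pairs[r, 1]] <- 0.6
  corr <- nearest_correlation(corr)
  base <- rnorm(d, 0, 0.5)                  # taxon-level unevenness
  mu <- matrix(base, n, d, byrow = TRUE)
  mu[, match(dominant, taxa)] <- ifelse(state == "dominated", 8, -1)
  # log_sd = 2.3: heavy-tailed per-sample blooms, so that (as in real genus
  # tables) most pool members exceed 5% relative abundance somewhere
  sim <- simulate_counts(n, taxa, basis_correlation = corr,
                         depth_mean = depth_mean, depth_sdlog = depth_sdlog,
                         log_mean = mu, log_sd = 2.3)
  counts <- sim$counts
  rownames(counts) <- paste0(participant, "_", substr(site, 1, 1))
  list(counts = counts,
       pairs = cbind(taxa[pairs[, 1]], taxa[pairs[, 2]]))
}
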