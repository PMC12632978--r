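# Fixtures are built in code: small registries and panels are written to
# tempfiles through the public TSV dialects and loaded back.

registry_header <- paste("binder_id", "target_receptor", "receptor_family",
                         "chain_class", "length_aa", "kd_nM", "origin",
                         "blocks_native_site", sep = "\t")

write_registry_tsv <- function(rows) {
  f <- tempfile(fileext = ".tsv")
  writeLines(c(registry_header, rows), f)
  f
}

# a 3-binder toy registry: two cytokine arms and one non-STAT arm
toy_registry <- function() {
  load_registry(write_registry_tsv(c(
    "a_bd\tgcommon\tcytokine_common\tcommon\t60\t5\trosetta\tTRUE",
    "b_bd\tIL4Ra\tcytokine_private\tprivate\t70\t20\tredesigned_agonist\tFALSE",
    "c_bd\tEGFR\tgrowth_factor\tnon_cytokine\t55\tNA\tprior_work\tFALSE")))
}

# write a FASTA for a registry with arbitrary deterministic sequences
toy_fasta <- function(registry) {
  f <- tempfile(fileext = ".fasta")
  b <- registry$binders
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  lines <- unlist(lapply(seq_len(nrow(b)), function(i) {
    c(paste0(">", b$binder_id[i]),
      paste(rep(aa, length.out = b$length_aa[i]), collapse = ""))
  }))
  writeLines(lines, f)
  f
}

# compact panel: two cell types expressing the toy receptors
toy_panel <- function() {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("cell_type\treceptor\tdensity",
               "alpha\tgcommon\t2000", "alpha\tIL4Ra\t1500",
               "beta\tgcommon\t1000", "beta\tIL4Ra\t0",
               "beta\tEGFR\t500"), f)
  load_cell_panel(f)
}

# single engineered-line panel expressing every registry receptor
u937_panel <- function() {
  p <- default_cell_panel(include_u937 = TRUE)
  p$density <- p$density["U937_like", , drop = FALSE]
  p
}

# prior-work subset used for pilot-scale enumeration
pilot_registry <- function() {
  reg <- default_registry()
  subset_registry(reg, reg$binders$binder_id[reg$binders$origin == "prior_work"])
}

# triplicate-mean control spread on the fluorescence scale, the noise floor
# handed to the dose-response classifier
control_noise_floor <- function(baseline = 100, cv = 0.15, seed = 123) {
  set.seed(seed)
  3 * stats::sd(baseline * rowMeans(matrix(novoscreen:::rlnorm_cv(600, cv),
                                           ncol = 3)))
}

pilot_ids <- function() {
  reg <- default_registry()
  reg$binders$binder_id[reg$binders$origin == "prior_work"]
}

toy_screen_parts <- function(seed = 1, p_active = c(gcommon = 0.9, .default = 0.5)) {
  reg <- toy_registry()
  lib <- enumerate_library(reg)
  panel <- toy_panel()
  truth <- make_ground_truth(lib, reg, panel, p_active = p_active, seed = seed)
  donors <- donor_profiles(3, colnames(panel$density), seed = seed)
  plan <- screen_plan(seed = seed)
  list(reg = reg, lib = lib, panel = panel, truth = truth,
       donors = donors, plan = plan)
}

named_ko_constructs <- function(lib) {
  pairs <- list(c("bcommon_bd", "gcommon_bd"), c("gcommon_bd", "gp130_bd"),
                c("IL7Ra_bd", "IFNAR1_bd"), c("IL21Ra_bd", "IFNAR1_bd"))
  ids <- vapply(pairs, function(p) paste(p[1], "2xGGS", p[2], sep = "__"),
                character(1))
  lib[match(ids, lib$construct_id), ]
}

ternary_truth_for <- function(lib, reg, panel, ids, efficacy = 5, seed = 1) {
  truth <- make_ground_truth(lib, reg, panel,
                             p_active = c(.default = 0), seed = seed)
  i <- match(ids, truth$construct_id)
  truth$mechanism[i] <- "ternary"
  truth$efficacy[i] <- efficacy
  truth
}
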