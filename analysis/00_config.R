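# Shared settings for the analysis workflow.
#
# The study conditions mirror the published cohorts (29 + 29 RRMS patients);
# the demo size below keeps a full desktop run to a few minutes. Raise
# N_PER_GROUP to 29 to run at the study scale.

library(lesionquant)

N_PER_GROUP <- 10
MASTER_SEED <- 42

CFG <- pipeline_config(n_per_group = N_PER_GROUP, seed = MASTER_SEED)

RESULTS_DIR <- "results"
SCRATCH_DIR <- "scratch"
dir.create(RESULTS_DIR, showWarnings = FALSE)
dir.create(file.path(SCRATCH_DIR, "masks"), recursive = TRUE, showWarnings = FALSE)

group_seed <- function(group) CFG$seed + ifelse(group == "pediatric", 0L, 104729L)

make_cohort <- function(group) {
  generate_cohort(N_PER_GROUP,
                  cohort_sampler(CFG$protocols[[group]],
                                 t1_core_fraction = CFG$phantom$t1_core_fraction,
                                 bias_field_amplitude = CFG$phantom$bias_field_amplitude),
                  seed = group_seed(group),
                  id_prefix = substr(group, 1, 3))
}
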