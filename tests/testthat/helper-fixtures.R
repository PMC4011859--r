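# Shared synthetic fixtures, built once per test run (generation + analysis
# of a multi-minute recording takes several seconds).

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# six pure stage segments, margin 0.2, epoch-aligned boundaries
fx_stage_plan <- function() {
  data.frame(label = c("1", "2", "3A", "3B", "4", "5"), duration = 60)
}

fx_stagerec <- function() fixture("stagerec", function() {
  syn <- synthesize_recording(sim_config(fx_stage_plan(), seed = 11))
  list(syn = syn, ana = analyze_record(syn$record))
})

# Fig-5-style progression with a brief HFT; three replicates
fx_fig5_plan <- function() {
  data.frame(label = c("baseline", "2", "HFT", "3A", "3B", "4", "5"),
             duration = c(30, 40, 5, 40, 40, 40, 40))
}

fx_fig5 <- function() fixture("fig5", function() {
  lapply(1:3, function(sd) {
    syn <- synthesize_recording(sim_config(fx_fig5_plan(), seed = sd))
    list(syn = syn, ana = analyze_record(syn$record))
  })
})

# baseline-heavy recording with one artifact of each class, two replicates
fx_artifact_plan <- function() {
  list(stage = data.frame(label = c("baseline", "2", "baseline"),
                          duration = c(120, 60, 120)),
       artifact = data.frame(kind = c("electrical", "grooming", "movement"),
                             onset = c(20, 50, 230),
                             duration = c(3, 30, 30)))
}

fx_artifacts <- function() fixture("artifacts", function() {
  p <- fx_artifact_plan()
  lapply(1:2, function(sd) {
    syn <- synthesize_recording(
      sim_config(p$stage, artifact_plan = p$artifact, seed = sd))
    list(syn = syn, ana = analyze_record(syn$record))
  })
})

# epoch-level truth vs prediction comparison table
fx_compare <- function(x) {
  merge(x$syn$truth$epochs, x$ana$epochs, by = "epoch_start",
        suffixes = c(".truth", ".pred"))
}

# simple diary helpers for severity tests
diary_rld <- function(intervals, dz = NA, death = NA) {
  seizure_diary("m1", "RLD", intervals, diazepam_time = dz,
                death_time = death)
}
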