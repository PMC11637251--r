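# Shared small fixtures, generated in code at test time.

tiny_cfg <- function(...) {
  args <- utils::modifyList(list(n_subjects_per_group = 2L,
                                 n_epochs_per_subject = 3L, seed = 11L),
                            list(...))
  do.call(sim_config, args)
}

# epochs of one group as a plain list, plus the planted truth
hc_epochs <- function(cfg) {
  ds <- simulate_dataset(cfg)
  subs <- Filter(function(s) s$group == "HC", ds$subjects)
  list(epochs = unlist(lapply(subs, `[[`, "epochs"), recursive = FALSE),
       states = unlist(lapply(subs, `[[`, "states"), recursive = FALSE),
       subjects = unlist(lapply(subs, function(s)
         rep(s$id, length(s$epochs)))),
       truth = ds$truth)
}

truth_templates <- function(truth) {
  structure(list(maps = truth$templates,
                 labels = LETTERS[seq_len(nrow(truth$templates))],
                 channels = default_channels_for(ncol(truth$templates))),
            class = "ms_templates")
}

default_channels_for <- function(n) eegms:::default_channel_names(n)

# fraction of samples on which two label sequences agree
label_agreement <- function(a, b) mean(a == b)
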