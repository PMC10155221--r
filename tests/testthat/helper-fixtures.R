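# Shared fixtures. Everything is generated in code on a small 16^3 grid so
# the unit tests stay fast; the acceptance tests use the full analysis
# grid where the contract demands it.

tiny_grid <- function() c(16L, 16L, 16L)

tiny_mask <- function() ellipsoid_mask(tiny_grid())

tiny_config <- function(regime = "single_study", ...) {
  defaults <- switch(regime,
    single_study = list(n_classes = 4L, n_tasks = 2L, n_subjects = 6L),
    multi_study = list(n_classes = 6L, n_studies = 3L, subjects_per_study = 8L),
    pretraining_corpus = list(n_classes = 6L, n_maps = 24L))
  args <- utils::modifyList(c(list(regime = regime,
                                   grid_shape = tiny_grid(), seed = 42L),
                              defaults),
                            list(...))
  do.call(synthetic_config, args)
}

# small labelled collection, preprocessed onto its grid
tiny_collection <- function(...) {
  cfg <- tiny_config("single_study", ...)
  mask <- config_mask(cfg)
  coll <- generate_labeled_collection(cfg)
  coll$maps <- preprocess_collection(coll$maps, mask)
  coll$mask <- mask
  coll$config <- cfg
  coll
}

# hand-built template with blobs confined to one region of the mask
manual_template <- function(class_id, centers, width = 10, amplitude = 6,
                            task = NULL) {
  structure(list(
    class_id = class_id,
    blobs = lapply(centers, function(ctr)
      list(center = as.integer(ctr), width = width, amplitude = amplitude)),
    parent_task = task
  ), class = "class_template")
}

# flatten all numeric leaves of a nested parameter list into one vector
param_vector <- function(params) {
  unlist(rapply(params, function(x) as.numeric(x), how = "unlist"))
}
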