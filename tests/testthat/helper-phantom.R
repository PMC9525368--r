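# Shared fixtures, built once per test run and memoised.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

test_atlas <- function() fixture("atlas48", function() make_atlas(seed = 1))

test_atlas_small <- function() {
  fixture("atlas32", function() {
    make_atlas(shape = c(32, 32, 32), voxel_size_mm = c(3, 3, 3), seed = 2)
  })
}

# a clean (noise-free, homogeneous, perfectly registered) subject at a
# given uniform load; same seed -> identical acquisition chain
clean_params <- function(a = 0, ...) {
  subject_params(amyloid_load = a, noise_sd = 0,
                 binding_texture_sd = 0, perfusion_texture_sd = 0,
                 misreg_vox = 0L, ...)
}

clean_subject <- function(a = 0, atlas = test_atlas(), seed = 1, ...) {
  simulate_subject(atlas, clean_params(a, ...), seed = seed)
}

# hand-built miniature scan for arithmetic oracles: voxel values and labels
# are supplied directly, bypassing the simulator
toy_scan <- function(labels, early, late, voxel_size_mm = c(1, 1, 1)) {
  lab <- array(labels, c(length(labels), 1L, 1L))
  atlas <- structure(
    list(label_map = lab, voxel_size_mm = voxel_size_mm,
         label_codes = atlas_label_codes, shell_frac = NULL,
         seed = NA_integer_, cache = new.env(parent = emptyenv())),
    class = "phantom_atlas"
  )
  structure(
    list(early = array(early, dim(lab)), late = array(late, dim(lab)),
         atlas = atlas, atrophied = NULL,
         meta = list(subject_id = "toy", age = 70, class_label = "negative",
                     misreg_shift = NULL)),
    class = "subject_scan"
  )
}

# small default cohort shared by comparison-stage tests
test_cohort_small <- function() {
  fixture("cohort_small", function() {
    simulate_cohort(test_atlas_small(),
                    cohort_spec(n_negative = 14, n_positive = 10, seed = 42))
  })
}

test_scores_small <- function() {
  fixture("scores_small", function() quantify_cohort(test_cohort_small()))
}
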