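# Shared fixtures, built once per test run and cached. All ensembles are
# generated at reduced scale (fewer replicates and/or a lighter template)
# compared to the 512 x 2 us reference protocol, to keep the suite fast;
# the full-scale ensemble is exercised in test-acceptance.R.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, .fixture_cache))
    assign(name, force(expr), .fixture_cache)
  get(name, .fixture_cache)
}

# default (hDAT-like, 559-bead) template
tpl_default <- function() fixture("tpl_default", build_protomer_template())

# light 138-bead template with the same helix layout and radii
tpl_small <- function() fixture("tpl_small",
                                build_protomer_template(n_helices = 12L,
                                                        beads_per_helix = 8L))

# mid-size planted ensemble: light template, 96 replicates, full 2 us
ens_mid <- function() fixture("ens_mid", generate_daft_ensemble(
  tpl_small(), default_interaction_map(),
  ensemble_config(n_replicates = 96L, duration = 2, seed = 301L)))

frames_mid <- function() fixture("frames_mid",
                                 orientation_frames(ens_mid()))

# default-template planted ensemble (smaller, for contact-map properties
# that depend on the full bead geometry)
ens_def <- function() fixture("ens_def", generate_daft_ensemble(
  tpl_default(), default_interaction_map(),
  ensemble_config(n_replicates = 48L, duration = 2, seed = 11L)))

# full-scale default ensemble for the acceptance criteria (512 replicates,
# default template) - generated once, reused by several acceptance tests
ens_full <- function() fixture("ens_full", generate_daft_ensemble(
  tpl_default(), default_interaction_map(),
  ensemble_config(n_replicates = 512L, duration = 2, seed = 1L)))

frames_full_final <- function() fixture("frames_full_final",
                                        orientation_frames(ens_full(), times = 2.0))

# a quick-capture config: protomers start close in a small box so that
# dimers form within a fraction of a microsecond
quick_cfg <- function(n_replicates = 24L, duration = 0.5, seed = 77L, ...) {
  ensemble_config(n_replicates = n_replicates, duration = duration,
                  box = c(12, 12), start_com_separation = 5.5,
                  min_start_clearance = 0.8, seed = seed, ...)
}

# planted centers of the default interaction map, symmetry partners included
default_centers <- function() {
  a <- expand_attractors(default_interaction_map())
  a[, c("beta", "chi")]
}

expect_wrapped_equal <- function(a, b, tol = 1e-6) {
  expect_lt(max(abs(ang_diff(a, b))), tol)
}
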