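## Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

## A quiet spec: no noise, no wander, no beat-level jitter — the generator
## is then exactly periodic per patient.
quiet_spec <- function(seed = 1, ...) {
  cohort_spec(noise_sd = 0, wander_amp = 0, aiv_sd = 0, seed = seed, ...)
}

## Tiny preprocessed cohort at a given class-effect scale.
tiny_beats <- function(effect_scale = 1, seed = 3) {
  fixture(sprintf("tiny_beats_%g_%d", effect_scale, seed), function() {
    spec <- preset_cohort("tiny", seed = seed,
                          effects = default_class_effects(effect_scale = effect_scale))
    cohort_segments(spec)
  })
}

tiny_detection_bundle <- function(effect_scale = 1, seed = 3) {
  fixture(sprintf("tiny_det_%g_%d", effect_scale, seed), function() {
    loc <- build_locating_dataset(tiny_beats(effect_scale, seed),
                                  selection_plan(10, 10, 2, seed = seed))
    build_detection_dataset(loc)
  })
}

## Full study-shaped cohort, preprocessed (the expensive fixture; built at
## most once per run).
table1_beats <- function(seed = 7) {
  fixture(sprintf("table1_beats_%d", seed), function() {
    cohort_segments(preset_cohort("table1", seed = seed))
  })
}

## Scaled-down training protocol used in all test-time learning runs: the
## full-scale protocol performs about 6 parameter updates per epoch
## (1920 training pieces / 300 per batch); at tiny scale the batch that
## preserves that update density is ~20. The epoch cap is 60 — about three
## times the observed convergence horizon on strongly separable tiny data —
## because train-loss patience rarely fires once the model keeps improving.
tiny_train_config <- function(...) {
  train_config(batch_size = 20, max_epochs = 60, patience = 20, ...)
}

## Brute-force Mann-Whitney U permutation oracle: enumerate all C(n+m, n)
## assignments of the pooled values to sample a.
brute_force_u_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(a); m <- length(b)
  r_all <- rank(pooled)
  u_obs <- sum(r_all[seq_len(n)]) - n * (n + 1) / 2
  combs <- utils::combn(n + m, n)
  us <- apply(combs, 2, function(idx) sum(r_all[idx]) - n * (n + 1) / 2)
  p_le <- mean(us <= u_obs)
  p_ge <- mean(us >= u_obs)
  list(u = u_obs, p = min(1, 2 * min(p_le, p_ge)))
}
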