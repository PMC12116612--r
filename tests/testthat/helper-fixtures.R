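# Shared fixtures: everything is generated in code at test time.

.fixture_env <- new.env(parent = emptyenv())

# Short-hold, study-rate parameters: keeps filtering cheap while preserving
# the 1000 Hz band semantics.
tiny_params <- function(n = 3L, seed = 42L, duration_s = 1.5, ...) {
  sim_params(n_patients = n, seed = seed, duration_s = duration_s, ...)
}

# Memoised small cohort (simulation is the slow part of the fixtures).
tiny_sim <- function(n = 3L, seed = 42L, duration_s = 1.5, ...) {
  key <- paste(n, seed, duration_s, ...)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- simulate_cohort(
      tiny_params(n, seed, duration_s, ...))
  }
  .fixture_env[[key]]
}

tiny_tensor_spec <- function(len = 150L) tensor_spec(100, len)

# Config with a receptive field that fits short tensors.
tiny_config <- function(kind = "tcn_lstm", conv_dropout = 0.1,
                        lstm_dropout = 0.1, ...) {
  model_config(kind, dilations = c(1L, 2L, 4L), n_filters = 4L,
               lstm_units = 6L, fc_nodes = c(8L, 4L), static_fc = c(6L, 3L),
               lstm_pool = 4L, conv_dropout = conv_dropout,
               lstm_dropout = lstm_dropout, ...)
}

# A synthetic supervised dataset with controllable signal, bypassing the
# cohort machinery (for split/train protocol tests).
fake_dataset <- function(n_patients, per_patient = 2L, T = 24L, seed = 7L,
                         target_name = "cobb_T", signal = TRUE) {
  with_seed <- function(s, code) { set.seed(s); force(code) }
  with_seed(seed, {
    n <- n_patients * per_patient
    pid <- rep(sprintf("F%03d", seq_len(n_patients)), each = per_patient)
    truth <- rep(runif(n_patients, 10, 30), each = per_patient)
    X <- array(rnorm(n * 8 * T), c(n, 8L, T))
    S <- cbind(feat = if (signal) truth + rnorm(n, 0, 1) else rnorm(n),
               noise = rnorm(n))
    Fm <- cbind(S, extra = rnorm(n))
    structure(list(X = X, S = S, F = Fm, y = matrix(truth, ncol = 1L),
                   patient_id = pid,
                   week = rep(c(0L, 24L), length.out = n),
                   exercise = rep(exercise_types(), length.out = n),
                   target_name = target_name,
                   tensor_spec = tensor_spec(100, T),
                   filter_spec = filter_spec()),
              class = "semg_dataset")
  })
}

make_recording <- function(patient_id = "P1", week = 0L,
                           exercise = "quadruped", T = 1500L, seed = 1L,
                           gen = function(T) matrix(rnorm(8 * T, 0, 20), 8L, T)) {
  set.seed(seed)
  emg_recording(patient_id, week, exercise, gen(T))
}

make_static <- function(patient_id = "P1", sex = "female",
                        curve_direction = "left", bmi = 17.3) {
  patient_static(patient_id, age = 14, sex = sex, bmi = bmi, risser = 2,
                 curve_direction = curve_direction)
}
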