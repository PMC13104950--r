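# shared fixture builders (everything generated in code; no stored data)

tiny_recording <- function(duration = 100, rates = c(1, 2), seed = 1) {
  set.seed(seed)
  units <- lapply(seq_along(rates), function(i)
    spike_train(sprintf("u%d", i),
                sort(runif(rpois(1, rates[i] * duration), 0, duration))))
  recording(units, duration = duration, area = "flM1", hemisphere = "left")
}

# homogeneous-Poisson spike train
poisson_train <- function(rate, duration, seed = NULL, id = "u1") {
  if (!is.null(seed)) set.seed(seed)
  spike_train(id, sort(runif(rpois(1, rate * duration), 0, duration)))
}

# spike train with a multiplicative rate gain inside [on, on + width] around
# each event (thinning construction)
gained_train <- function(baseline, events, gain, width = 0.2, duration,
                         seed = NULL, id = "u1") {
  if (!is.null(seed)) set.seed(seed)
  st <- sort(runif(rpois(1, baseline * gain * duration), 0, duration))
  inwin <- Reduce(`|`, lapply(events, function(e) st >= e & st < e + width))
  keep <- inwin | (runif(length(st)) < 1 / gain)
  spike_train(id, st[keep])
}

# minimal kinematics frame for distance tests
kin_frame <- function(l, r, n, l_valid = TRUE, r_valid = TRUE, n_valid = TRUE,
                      nframes = 1, dt = 0.005) {
  data.frame(time_s = (seq_len(nframes) - 1) * dt,
             lx = l[1], ly = l[2], lz = l[3],
             rx = r[1], ry = r[2], rz = r[3],
             nx = n[1], ny = n[2], nz = n[3],
             l_valid = l_valid, r_valid = r_valid, n_valid = n_valid)
}

# random PSD matrix
random_psd <- function(n, rank = n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  A <- matrix(rnorm(n * rank), n, rank)
  tcrossprod(A) / rank
}

# random orthonormal rows (k x n)
random_orthonormal <- function(k, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  t(qr.Q(qr(matrix(rnorm(n * k), n, k))))
}

# quick behavior + spikes bundle for pipeline-level tests
small_bundle <- function(mode = "invariant", n_units = 20, cycles = 6,
                         seed = 1, gain_hz = 6, profile = "transient") {
  beh <- generate_kinematics(behavior_config(cycles_per_condition = cycles),
                             seed = seed)
  ev <- beh$events[beh$events$kind == "transport", ]
  sp <- generate_spikes(beh$kinematics, ev,
                        population_config(n_units = n_units, mode = mode,
                                          gain_hz = gain_hz, profile = profile),
                        seed = seed + 1)
  list(recording = sp$recording, kinematics = beh$kinematics, events = ev,
       behavior = beh, truth = sp$truth)
}

# scipy linprog transportation-LP oracle, batched over instances.
# instances: list of list(p =, q =); returns vector of optimal costs.
scipy_emd_oracle <- function(instances, ground) {
  infile <- tempfile(fileext = ".json")
  outfile <- tempfile(fileext = ".json")
  jsonlite::write_json(list(ground = ground, instances = instances), infile,
                       digits = NA, auto_unbox = FALSE)
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import json, sys",
    "import numpy as np",
    "from scipy.optimize import linprog",
    "spec = json.load(open(sys.argv[1]))",
    "D = np.array(spec['ground'])",
    "n = D.shape[0]",
    "A = []",
    "for i in range(n):",
    "    row = np.zeros((n, n)); row[i, :] = 1; A.append(row.ravel())",
    "for j in range(n - 1):",
    "    col = np.zeros((n, n)); col[:, j] = 1; A.append(col.ravel())",
    "A = np.array(A)",
    "out = []",
    "for inst in spec['instances']:",
    "    p = np.array(inst['p'], dtype=float); q = np.array(inst['q'], dtype=float)",
    "    q = q * p.sum() / q.sum()",
    "    b = np.concatenate([p, q[:-1]])",
    "    r = linprog(D.ravel(), A_eq=A, b_eq=b, bounds=(0, None), method='highs')",
    "    assert r.status == 0, r.message",
    "    out.append(r.fun)",
    "json.dump(out, open(sys.argv[2], 'w'))"), script)
  status <- system2("python", c(script, infile, outfile))
  stopifnot(status == 0)
  unlist(jsonlite::read_json(outfile, simplifyVector = TRUE))
}
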