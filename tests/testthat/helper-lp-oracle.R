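# Independent LP oracle: scipy.optimize.linprog (HiGHS) through the
# system python, batched over a list of FBA problems. A completely
# different solver and encoding from the package's simplex core.

oracle_linprog <- function(problems) {
  infile <- tempfile(fileext = ".json")
  outfile <- tempfile(fileext = ".json")
  payload <- lapply(problems, function(p) {
    list(S = as.vector(t(p$S)), m = nrow(p$S), n = ncol(p$S),
         lb = p$lb, ub = p$ub, c = as.numeric(seq_along(p$lb) == p$obj_idx))
  })
  jsonlite::write_json(payload, infile, digits = NA, auto_unbox = TRUE)
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import json, sys",
    "import numpy as np",
    "from scipy.optimize import linprog",
    "probs = json.load(open(sys.argv[1]))",
    "out = []",
    "for p in probs:",
    "    S = np.array(p['S'], dtype=float).reshape(p['m'], p['n'])",
    "    res = linprog(c=[-x for x in p['c']], A_eq=S, b_eq=[0.0]*p['m'],",
    "                  bounds=list(zip(p['lb'], p['ub'])), method='highs')",
    "    status = {0: 'optimal', 2: 'infeasible', 3: 'unbounded'}.get(res.status, 'error')",
    "    out.append({'status': status,",
    "                'obj': (-res.fun) if res.status == 0 else None})",
    "json.dump(out, open(sys.argv[2], 'w'))"), script)
  rc <- system2("python", c(script, infile, outfile), stdout = TRUE,
                stderr = TRUE)
  if (!file.exists(outfile)) {
    stop("LP oracle failed: ", paste(rc, collapse = "\n"))
  }
  jsonlite::read_json(outfile)
}

# Random small metabolic network whose LP is always feasible (0 is within
# every bound), as both raw matrices and a MetabolicModel.
random_network <- function(seed) {
  set.seed(seed)
  m <- sample(2:5, 1)
  n <- sample(3:12, 1)
  S <- matrix(0, m, n)
  for (j in seq_len(n)) {
    k <- sample(1:min(3, m), 1)
    rows <- sample(m, k)
    S[rows, j] <- sample(c(-2, -1, 1, 2), k, replace = TRUE)
  }
  lb <- sample(c(-10, -5, 0), n, replace = TRUE)
  ub <- sample(c(0, 5, 10), n, replace = TRUE)
  obj_idx <- sample(n, 1)
  mets <- lapply(seq_len(m), function(i) metabolite(paste0("m", i)))
  rxns <- lapply(seq_len(n), function(j) {
    st <- S[, j]
    names(st) <- paste0("m", seq_len(m))
    reaction(paste0("r", j), st[st != 0], lower_bound = lb[j],
             upper_bound = ub[j])
  })
  model <- metabolic_model(mets, rxns, paste0("r", obj_idx),
                           id = paste0("rand", seed))
  list(S = S, lb = lb, ub = ub, obj_idx = obj_idx, model = model)
}
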