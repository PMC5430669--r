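# Independent coalescent oracle: msprime driven through the system
# python, configured to the package's scaled rates (haploid demes of
# size 1 so a pair coalesces at rate 1 per time unit; mutation rate
# theta_locus / 2 on a continuous genome).

msprime_available <- function() {
  nzchar(Sys.which("python")) &&
    system2("python", c("-c", shQuote("import msprime")),
            stdout = FALSE, stderr = FALSE) == 0
}

msprime_script <- '
import json, sys
import msprime

nw, ne, theta, T_coal, M, tau, model, reps, seed, out = sys.argv[1:]
nw, ne, reps, seed = int(nw), int(ne), int(reps), int(seed)
theta, T_coal, M, tau = float(theta), float(T_coal), float(M), float(tau)

res = {"S": [], "pw": [], "pe": [], "sh": [], "fx": []}
if T_coal == 0 and ne == 0:
    dem = None
else:
    dem = msprime.Demography()
    dem.add_population(name="W", initial_size=1)
    dem.add_population(name="E", initial_size=1)
    dem.add_population(name="ANC", initial_size=1)
    if model in ("ongoing", "secondary") and M > 0:
        dem.set_symmetric_migration_rate(["W", "E"], M / 2)
        if model == "secondary" and tau < 1:
            dem.add_symmetric_migration_rate_change(
                time=tau * T_coal, populations=["W", "E"], rate=0)
    dem.add_population_split(time=T_coal, derived=["W", "E"], ancestral="ANC")
    dem.sort_events()

for i in range(reps):
    if dem is None:
        ts = msprime.sim_ancestry(
            samples=[msprime.SampleSet(nw, ploidy=1)], ploidy=1,
            population_size=1, random_seed=seed + 2 * i + 1)
    else:
        ts = msprime.sim_ancestry(
            samples=[msprime.SampleSet(nw, population="W", ploidy=1),
                     msprime.SampleSet(ne, population="E", ploidy=1)],
            ploidy=1, demography=dem, random_seed=seed + 2 * i + 1)
    mts = msprime.sim_mutations(ts, rate=theta / 2, random_seed=seed + 2 * i + 2,
                                discrete_genome=False)
    pw = pe = sh = fx = 0
    for var in mts.variants():
        g = var.genotypes
        cw = int((g[:nw] > 0).sum())
        ce = int((g[nw:] > 0).sum()) if ne > 0 else 0
        poly_w = 0 < cw < nw
        poly_e = 0 < ce < ne if ne > 0 else False
        if poly_w and poly_e: sh += 1
        elif poly_w: pw += 1
        elif poly_e: pe += 1
        elif (cw == nw and ce == 0) or (cw == 0 and ce == ne): fx += 1
    res["S"].append(int(mts.num_sites))
    res["pw"].append(pw); res["pe"].append(pe)
    res["sh"].append(sh); res["fx"].append(fx)

with open(out, "w") as fh:
    json.dump(res, fh)
'

run_msprime <- function(nw, ne, theta_locus, T_coal, M, tau, model,
                        reps, seed) {
  script <- tempfile(fileext = ".py")
  writeLines(msprime_script, script)
  out <- tempfile(fileext = ".json")
  status <- system2("python",
                    c(script, nw, ne, theta_locus, T_coal, M, tau, model,
                      reps, seed, out),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0) stop("msprime oracle run failed")
  jsonlite::fromJSON(out)
}
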