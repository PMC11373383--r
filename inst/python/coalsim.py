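"""Coalescent simulation bridge.

Reads a JSON configuration (path given as argv[1]) describing one scenario
and a list of per-replicate seeds, runs msprime, and prints ms-dialect text
(segsites / positions / 0-1 haplotype rows) to stdout.

Engine-level parameters (generations, per-bp rates) are computed on the R
side; this script only composes msprime calls:

  * bottleneck: single population with piecewise size changes; the sweep
    (when requested) is a conditioned frequency-trajectory phase inserted at
    its fixation time.
  * structure ("migration" confounders): two equal demes, no gene flow,
    merging join_gen generations ago.  Each deme is simulated separately up
    to the join (the sweep, if older than the join, happens after the merge;
    if younger, it runs deme-locally in deme 1), the partial tree sequences
    are disjoint-unioned, and ancestry is completed in the merged
    population.  This sidesteps the single-population restriction of the
    sweep model without changing the model being simulated.
  * hotspot: recombination rate map with a fold-elevated central interval.

Replicates with fewer segregating sites than min_snps are retried with a
fresh derived seed up to max_retries times.
"""

import json
import sys
import warnings

import numpy as np
import msprime
import tskit

warnings.simplefilter("ignore")  # union drops population metadata; harmless


def flatten_populations(ts):
    """Relabel all nodes to population 0 so msprime will accept the tree
    sequence as single-population initial state."""
    t = ts.dump_tables()
    t.nodes.population = np.zeros(ts.num_nodes, dtype=np.int32)
    t.populations.truncate(0)
    t.populations.metadata_schema = tskit.MetadataSchema.null()
    t.populations.add_row(b"")
    return t.tree_sequence()


def sweep_model(cfg, N0):
    sw = cfg.get("sweep")
    return msprime.SweepGenicSelection(
        position=sw["position"],
        start_frequency=1.0 / (2 * N0),
        end_frequency=1.0 - 1.0 / (2 * N0),
        s=sw["s"],
        dt=1.0 / (40 * N0),
    )


def model_sequence(cfg, N0, wait_gen):
    """Standard coalescent until wait_gen, then the sweep, then standard."""
    return [
        msprime.StandardCoalescent(duration=wait_gen),
        sweep_model(cfg, N0),
        msprime.StandardCoalescent(),
    ]


def recomb_map(cfg):
    hs = cfg.get("hotspot")
    r = cfg["recomb_rate"]
    L = cfg["L"]
    if hs is None:
        return r
    return msprime.RateMap(
        position=[0.0, hs["left"], hs["right"], L],
        rate=[r, hs["fold"] * r, r],
    )


def bottleneck_demography(cfg):
    N0 = cfg["N0"]
    dem = msprime.Demography()
    dem.add_population(initial_size=N0)
    bn = cfg.get("bottleneck")
    if bn is not None:
        dem.add_population_parameters_change(
            time=bn["start_gen"], initial_size=bn["size"], population=0)
        dem.add_population_parameters_change(
            time=bn["end_gen"], initial_size=N0, population=0)
    return dem


def simulate_panmictic(cfg, seeds):
    """Single population (possibly with size changes / hotspot map)."""
    N0 = cfg["N0"]
    model = None
    if "sweep" in cfg and cfg["sweep"] is not None:
        model = model_sequence(cfg, N0, cfg["sweep"]["fix_gen"])
    return msprime.sim_ancestry(
        samples=cfg["samples"],
        demography=bottleneck_demography(cfg),
        sequence_length=cfg["L"],
        recombination_rate=recomb_map(cfg),
        discrete_genome=False,
        model=model,
        random_seed=seeds[0],
    )


def simulate_structured(cfg, seeds):
    """Two demes of size N0, no migration, merged join_gen generations ago.
    Sampling is split 50/50.  A sweep younger than the join runs in deme 1
    only; a sweep older than the join runs in the merged population."""
    N0 = cfg["N0"]
    L = cfg["L"]
    join_gen = cfg["structure"]["join_gen"]
    sw = cfg.get("sweep")
    rmap = recomb_map(cfg)
    half = cfg["samples"] // 2

    def deme(seed, with_sweep):
        model = None
        if with_sweep:
            model = model_sequence(cfg, N0, sw["fix_gen"])
        return msprime.sim_ancestry(
            samples=half, population_size=N0, sequence_length=L,
            recombination_rate=rmap, discrete_genome=False,
            model=model, end_time=join_gen, random_seed=seed)

    local_sweep = sw is not None and sw["fix_gen"] < join_gen
    ts1 = deme(seeds[0], local_sweep)
    ts2 = deme(seeds[1], False)
    u = ts1.union(ts2, node_mapping=np.full(ts2.num_nodes, tskit.NULL),
                  add_populations=False)
    u = flatten_populations(u)
    model = None
    if sw is not None and not local_sweep:
        model = model_sequence(cfg, N0, sw["fix_gen"] - join_gen)
    return msprime.sim_ancestry(
        initial_state=u, population_size=N0, recombination_rate=rmap,
        discrete_genome=False, model=model, random_seed=seeds[2])


def one_replicate(cfg, seed):
    min_snps = cfg.get("min_snps", 0)
    retries = cfg.get("max_retries", 10)
    for attempt in range(retries + 1):
        rng = np.random.RandomState((seed + 999983 * attempt) % (2**31 - 1))
        seeds = rng.randint(1, 2**31 - 2, size=4)
        if "structure" in cfg and cfg["structure"] is not None:
            ts = simulate_structured(cfg, seeds)
        else:
            ts = simulate_panmictic(cfg, seeds)
        ts = msprime.sim_mutations(ts, rate=cfg["mut_rate"],
                                   random_seed=seeds[3],
                                   discrete_genome=False)
        if ts.num_sites >= min_snps:
            return ts
    raise RuntimeError(
        f"replicate seed {seed}: fewer than {min_snps} SNPs after "
        f"{retries + 1} attempts")


def emit_ms(ts, L, out):
    pos = np.array([s.position for s in ts.sites()]) / L
    G = ts.genotype_matrix()  # sites x samples
    G = np.minimum(G, 1)      # infinite-sites: binary by construction
    out.write("//\n")
    out.write(f"segsites: {G.shape[0]}\n")
    out.write("positions: " + " ".join(f"{p:.8f}" for p in pos) + "\n")
    rows = (G.T + ord("0")).astype(np.uint8)
    for i in range(rows.shape[0]):
        out.write(rows[i].tobytes().decode("ascii") + "\n")
    out.write("\n")


def main():
    with open(sys.argv[1]) as fh:
        cfg = json.load(fh)
    out = sys.stdout
    nsam = cfg["samples"] * 2
    out.write(f"coalsim {nsam} {len(cfg['seeds'])} class={cfg['class']}\n")
    out.write(" ".join(str(s) for s in cfg["seeds"][:3]) + "\n\n")
    for seed in cfg["seeds"]:
        ts = one_replicate(cfg, int(seed))
        emit_ms(ts, cfg["L"], out)


if __name__ == "__main__":
    main()
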