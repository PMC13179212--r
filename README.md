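# bathyfd

Trait-based functional diversity of reef-fish communities along depth
gradients.

Reef-fish assemblages turn over taxonomically from shallow (altiphotic,
< 40 m) through mesophotic (40–130 m) and rariphotic (130–300 m) reefs to the
deep-sea boundary. `bathyfd` asks whether those turnovers are *functional*:
it takes a species × categorical-trait table (multi-valued cells allowed) and
long-format transect observations (site, depth, transect, length, species,
count), and computes every stage of a trait-based depth analysis for
community ecologists working on reef zonation, environmental filtering, and
deep-reef vulnerability.

## What it computes

* **Fuzzy binary trait coding** — each trait spread into one 0/1 column per
  category, columns of a trait with *k* categories weighted 1/*k*; species
  with identical signatures collapse into *functional entities*
  (`expand_traits()`, `derive_entities()`, `entity_redundancy()`).
* **Trait space** — weighted Gower dissimilarity
  `d(i,j) = Σ w_k |x_ik − x_jk| / Σ w_k`, the Cailliez additive-constant
  correction, and principal coordinates analysis
  (`gower_dist()`, `cailliez_correct()`, `pcoa_space()`,
  `build_trait_space()`).
* **Community metrics** per 10-m site × depth-bin community —
  community-weighted means (`CWM_k = Σ √a_s x_sk / Σ √a_s`), convex-hull
  functional richness (FRic), minimum-spanning-tree evenness (FEve),
  dispersion (FDis), Rao's quadratic entropy `Q = Σ d_ij p_i p_j`, Simpson
  diversity `D = 1 − Σ p_i²` and functional redundancy `R = D − Q`, plus
  species/entity rarefaction (`community_metrics()`, `cwm()`,
  `rarefaction()`).
* **Depth structure** — site-specific depth-zone schemes, the 75 %
  abundance-share depth-affinity classifier, and per-zone / per-affinity
  trait-space hulls and centroids (`zone_scheme()`, `depth_affinities()`,
  `zone_trait_summary()`, `affinity_trait_summary()`).
* **Break detection** — trait-category frequency profiles per bin,
  Bray–Curtis dissimilarity, Ward dendrograms, SIMPROF permutation tests and
  PERMANOVA (`trait_frequency_profiles()`, `simprof()`,
  `deepest_split_depth()`, `permanova_profiles()`).
* **Depth trends** — loess smoothers with permutation p-values, on the logit
  scale for CWM proportions (`loess_trend()`, `cwm_trend()`).
* **Synthetic surveys** — a generator of multi-site, depth-structured
  communities with trait-dependent environmental filtering, configurable
  community-break depths and full ground truth (`synthetic_config()`,
  `generate_communities()`).

`run_pipeline()` chains all stages and writes CSV/JSON/Newick outputs plus a
machine-readable run log.

## Worked example

```r
library(bathyfd)

# a synthetic 2-island survey, 0-450 m, 120 species, pool turnover at 200 m
cfg <- synthetic_config(n_species = 120, n_sites = 2)
gen <- generate_communities(cfg, seed = 42)

res <- run_pipeline(gen$traits, gen$observations,
                    config = list(seed = 42), effort = gen$effort)

res$space$space
#> Trait space: 120 species, 118 axes
#>   first axes capture 9.4% + 7.5% of trait variation
#>   Cailliez constant: 0.57

head(res$metrics[, c("community_id", "species_richness", "fric", "feve",
                     "fdis", "redundancy")], 3)
#>   community_id species_richness  fric  feve  fdis redundancy
#> 1     site1_d0               53 0.275 0.872 0.626      0.661
#> 2    site1_d10               50 0.275 0.852 0.626      0.658
#> 3    site1_d20               51 0.275 0.853 0.626      0.658

res$simprof
#> SIMPROF: 6 significant cluster(s) over 45 communities (alpha = 1e-07)
deepest_split_depth(res$simprof, pool_sites(res$communities)$info$depth_lower)
#> [1] 200

res$permanova[1, c("term", "r2", "pseudo_f", "p")]
#>   term    r2 pseudo_f     p
#> 1 zone 0.974      586 0.001

res$trends$fric$pooled
#> Trend fit: R2 = 0.599 , permutation p = 0.005 (span 0.75 , degree 2 )
```

The trait space spreads the 120 species by their trait combinations (the
Cailliez constant 0.57 is the additive correction that makes the Gower
matrix embeddable); the per-bin metrics show flat richness within the shallow
pool; SIMPROF finds the trait-composition break exactly at the generated
200-m pool turnover, and depth zone explains 97 % of the Bray–Curtis
variation in trait profiles.

Depth affinities are more informative under the graded (`"gaussian"`)
response shape, where species have individual depth preferences:

```r
cfg_g <- synthetic_config(n_species = 120, n_sites = 2,
                          response_shape = "gaussian")
gen_g <- generate_communities(cfg_g, seed = 42)
comm <- bin_depths(gen_g$observations, effort = gen_g$effort)
aff <- depth_affinities(species_zone_profiles(comm, cfg_g$scheme))
head(aff[, c("species", "affinity", "share")], 2)
#>   species                          affinity share
#> 1   sp001 lower_mesophotic-upper_rariphotic 0.808
#> 2   sp002                        generalist 0.899
```

`sp001` holds 81 % of its abundance across the lower-mesophotic +
upper-rariphotic pair of zones, so the 75 % rule labels it a two-zone
depth generalist of that range.

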