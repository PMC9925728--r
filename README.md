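# antioxscan

Comparative-genomic annotation of the three hydrogen-peroxide-scavenging
antioxidant enzyme families in animal proteomes — monofunctional **catalase
(CAT)**, **peroxiredoxin (PRX)** and **glutathione peroxidase (GPX)** — plus
the **sulfiredoxin (SRX)** reductant that reactivates hyperoxidized typical
2-Cys peroxiredoxins.

The package is aimed at comparative genomicists and redox biologists who
want a reproducible, auditable census of these gene families across a set of
predicted proteomes, starting from the two inputs every such survey already
has: amino-acid FASTA files and a HMMER3 `hmmscan --domtblout` table of Pfam
hits.

## What it does

The pipeline is the classic domain-then-motif filter chain:

1. **Domain architecture** (`run_scan`). Candidates are nominated from Pfam
   domain content: CAT requires both PF00199 (catalase) and PF06628
   (catalase_rel); PRX requires PF00578 plus at least one of PF08534 and
   PF10417; GPX requires PF00255 (GSHPx); SRX requires PF02195 (ParB-like
   nuclease). Hits are thresholded at an independent e-value of 1e-5 by
   default; all rules and thresholds are configurable.
2. **Catalytic-site motifs** (`run_classify`). A restricted motif grammar
   (fixed residues, alternations `[TS]`, bounded gaps `X{0,60}`) drives the
   filters: PRX candidates must carry the strictly conserved peroxidatic
   cysteine motif `PXXX[TS]XXC` (C_P); SRX competence additionally requires
   the N-terminal binding motif `F[SG]GCHR`; PRX6 is annotated for the
   phospholipase A2 triad (ordered H…S…D) and the lipase motif `GXSXG`;
   AhpC-PRX1 for the hyperoxidation-sensitivity motifs GGLG and YF and the
   modulating a/b motifs; the resolving cysteine (C_R) is typed as present /
   substituted (e.g. the valine substitution seen in some sponge PRX5) /
   absent.
3. **Subfamily classification.** PRX subfamilies (AhpC-PRX1, PRX5, PRX6) are
   called from the active-site sequence: a ±7-residue window around C_P is
   scored against position-specific profiles (mean log-odds vs a uniform
   background, with a margin threshold). GPX groups (GPX1/2, GPX3/5/6,
   GPX4/PHGPX, GPX7/8) are called phylogenetically, by placement inside
   labelled reference clades. GPX catalysis is typed selenium-dependent
   (Sec/U at the catalytic tetrad) or cysteine-dependent.
4. **Trees** (`run_tree`). Alignment columns with more than 50% gaps are
   removed (the 50% boundary column is kept), pairwise p- or
   Poisson-corrected distances are computed over mutually ungapped columns,
   a neighbor-joining tree is built with column-resampling bootstrap
   supports, and each query leaf is assigned the label of its smallest
   enclosing pure reference clade. Externally built maximum-likelihood
   trees in newick format are accepted as a drop-in replacement.
5. **Census.** Per species: unique accepted sequences per category (CAT,
   AhpC-PRX1, PRX5, PRX6, GPX) with exact-duplicate counts reported
   separately (`2^1`-style), and a tri-state SRX status — *competent*
   (domain + motif), *domain_only*, or *absent*.

A seeded synthetic-proteome generator (`generate_dataset`,
`generate_subfamily_alignment`) plants family members, motifs, decoys and
lesions with a full truth ledger, so the whole pipeline is testable without
downloading genomes.

## Worked example

```r
library(antioxscan)

cfg   <- synthetic_config(seed = 1, n_species = 4)   # 4 synthetic proteomes
ds    <- generate_dataset(cfg)
paths <- write_dataset(ds, "demo")                   # FASTA + domtblout + ledger
res   <- run_classify(paths$manifest, paths$domtblout, "demo/out")
res$census
#> antioxidant enzyme census (unique counts, ^duplicates):
#>      CAT AhpC-PRX1 PRX5 PRX6 GPX
#> sp01 2^1 3         1    2    4
#> sp02 2^1 3^1       1^1  2    4
#> sp03 2   3         1    2    4^1
#> sp04 2   3         1    2    4
```

Each cell is the number of unique accepted sequences; the superscript is the
number of additional exact sequence variants (e.g. `2^1` = two unique
catalases, one of which has one identical copy). Dashes mark categories with
no accepted member. `res$srx` holds the per-species SRX status, and
`demo/out/` contains the census (TSV + JSON), a per-protein evidence JSON,
an audit table in which every input sequence appears exactly once (accepted,
rejected with reasons, or duplicate), and per-stage funnel logs.

Motif-level functions are directly usable too:

```r
find_cp("MKPVDFTFVCRLA")
#> $start 3   $end 10   $cp_pos 10   $match "PVDFTFVC"   $n_matches 1
```

A thin command-line wrapper ships in `inst/cli/antioxscan.R`
(subcommands `scan`, `classify`, `tree`, `simulate`).

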