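# GeneFamSelect

Feature selection for high-dimensional nonnegative gene matrices by
combining **nonnegative matrix factorization (NMF)** with **ReliefF**
instance-based feature weighting, together with the surrounding pipeline:
construction of species × gene-family copy-number matrices from genome
annotation, baseline selectors (ReliefF, PCA-ReliefF, SVM-RFE with an mRMR
prefilter), and a leakage-safe cross-validated evaluation harness.

## The problem

Gene-family copy numbers — how many members of each family a genome
carries — vary widely across species and carry phenotypic signal (for
example, feeding habit in insects). Tallied across hundreds of species and
thousands of families (or across microarray probes and patients) the result
is a classic *m ≫ n* matrix: thousands of nonnegative features, under two
hundred samples, most features irrelevant or redundant. Classifiers built
directly on such matrices overfit; univariate filters ignore redundancy.
GeneFamSelect is for researchers who need a small, named set of
class-informative features from such a matrix before classification.

## The method

Given a nonnegative matrix **V** (m features × n samples) with a class
label per sample:

1. **NMF.** Factorize V ≈ WH with W (m × r) and H (r × n) nonnegative, by
   minimizing ‖V − WH‖²_F with the classical multiplicative updates

       W ← W ⊙ (VHᵀ) / (WHHᵀ),   H ← H ⊙ (WᵀV) / (WᵀWH)

   (⊙ and the fraction element-wise). Columns of W are *metagenes*; each
   column of H encodes a sample in metagene space. The updates preserve
   nonnegativity and never increase the objective.

2. **ReliefF on the metagene encodings.** Each of the r rows of H is a
   candidate feature over samples. For every sample, ReliefF finds its k
   nearest same-class neighbours (hits) and k nearest neighbours in every
   other class (misses), and scores each feature by

       w_f += − mean diff(f, x, hits) + Σ_c P(c)/(1−P(class(x))) · mean diff(f, x, misses_c)

   with min–max-normalized differences, averaged over samples. Metagenes
   that separate the classes score high.

3. **Back-mapping (gene mode).** Each metagene distributes its positive
   ReliefF weight over the original features proportionally to its loading
   column: score(f) = Σ_j max(w_j, 0) · W[f,j] / ‖W[·,j]‖₁. The top-n
   features — actual gene families — are reported. (`mode = "component"`
   returns the top metagenes instead.)

Performance is judged by stratified five-fold cross-validation, repeated,
with selection re-fit inside every training fold, reporting ACC, SEN, SPE
and the pairwise (rank) AUC:

    AUC = (#{score⁺ > score⁻} + ½·#ties) / (n⁺ · n⁻)

## Worked example

```r
library(GeneFamSelect)

## 500 gene families x 80 species, negative-binomial copy numbers,
## 5 planted informative families (mean shifted by 3 baseline SDs)
sim <- simulatePlantedMatrix(nFeatures = 500, nSamples = 80,
                             nInformative = 5, effectSize = 3,
                             countModel = "negbinom", seed = 42)
plantedFeatures(sim)
#> [1]  49  74 153 321 485

sel <- nmfRelieffSelect(sim, rank = 20, nSelect = 5, mode = "gene",
                        seed = 42)
sel
#> SelectionResult [nmf_relieff]: 5 features
#>   top: f74=0.004484 f321=0.003029 f49=0.002633 f153=0.002349 f485=0.002106
plantedRecovery(sel, sim)
#> [1] 1

## honest performance estimate: selection re-fit inside every fold
crossValidate(sim,
              selector = selectorSpec("nmf_relieff", nSelect = 5,
                                      rank = 20, mode = "gene"),
              classifier = "svm", nFolds = 5, nRepeats = 3, seed = 42)
#> EvalReport: svm classifier, 5 folds x 3 repeats (metric convention: standard)
#>   ACC = 0.9500 (SE 0.0164)
#>   SEN = 0.9000 (SE 0.0327)
#>   SPE = 1.0000 (SE 0.0000)
#>   AUC = 0.9969 (SE 0.0031)
```

All five planted families are recovered (`f49, f74, f153, f321, f485`),
and the cross-validated SVM on the five selected families classifies the
80 samples at 95% accuracy. The scores are the per-family shares of the
discriminative metagenes' ReliefF weight, so they sum over all features to
the total positive component weight.

Building a real matrix instead of a simulated one:

```r
iso <- selectLongestIsoform("annotation.gff3", "transcripts.fa")
keep <- filterAssemblies(readAssemblyStats("assembly_stats.tsv"))  # N50 >= 400 kb
gfm <- buildFamilyMatrix(readFamilyAssignments("families.tsv"),
                         speciesOrder = keep$species_id,
                         labels = speciesLabels)
data <- asLabeledMatrix(gfm)
```

## Command line

`inst/cli/genefamselect.R` exposes the pipeline as subcommands
(`build-matrix`, `simulate`, `select`, `evaluate`, `sweep`), each writing a
`.provenance.json` (parameters, seed, package version, input checksums)
next to its output:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/genefamselect.R", package="GeneFamSelect"))')" \
    select --in matrix.tsv --method nmf-relieff --rank 20 --n-select 50 \
    --seed 1 --out selection.tsv
```

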