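{"format":"mbcmsm-tree","version":1,"nCycles":3,"nWalkers":3,"tauWE":1,"states":[[0,1,3],[1,2,3],[0,3,4]],"weights":[[0.4,0.2,0.4],[0.4,0.2,0.4],[0.6,0.2,0.2]],"parents":[[0,0,0],[1,2,3],[1,3,3]],"cloneFrac":[[1,1,1],[1,1,1],[1,0.5,0.5]],"squashes":[{"cycle":2,"walker":2,"frac":1,"into":1}],"fates":[["CONTINUED","CONTINUED","CONTINUED"],["KEPT_MERGE(2)","SQUASHED(1)","CLONED(2)"],["CONTINUED","CONTINUED","CONTINUED"]],"meta":{"nStates":5,"fixture":"squashAfterOneStep"}}
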