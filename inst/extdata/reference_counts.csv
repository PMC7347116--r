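group,label,holdout_fold,test_fold,optimal_epoch,optimal_brightness,optimal_area,tp,fp,fn,printed_f1
test,fold0,0,1,13,240,150,78,22,29,0.754
test,fold1,1,2,2,120,700,78,4,25,0.843
test,fold2,2,3,1,246,400,94,17,14,0.858
test,fold3,3,4,5,220,300,73,17,30,0.756
test,fold4,4,0,5,210,20,126,29,49,0.764
holdout,fold0,0,1,NA,NA,NA,119,41,56,0.710
holdout,fold1,1,2,NA,NA,NA,71,21,36,0.714
holdout,fold2,2,3,NA,NA,NA,72,12,31,0.770
holdout,fold3,3,4,NA,NA,NA,91,27,17,0.805
holdout,fold4,4,0,NA,NA,NA,61,32,42,0.622
human,scorer1,NA,NA,NA,NA,NA,34,10,11,0.764
human,scorer2,NA,NA,NA,NA,NA,95,10,41,0.788
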