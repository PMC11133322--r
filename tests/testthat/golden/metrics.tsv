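metric	id	value
sign_accuracy_posterior	all	0.9166666667
knockout_rank	KO_TF001	          1
knockout_rank	KO_TF002	          1
knockout_rank	KO_TF003	          1
qs_improvement	TF001	-0.05126237006
qs_improvement	TF002	0.1532996525
qs_improvement	TF003	-0.04690195397
qs_improvement	TF004	-0.102160725
qs_improvement	TF005	-0.04436716305
rbo	S001	0.9637973333
rbo	S002	0.9837973333
rbo	S003	          1
rbo	S004	     0.9702
rbo	S005	0.9688913733
rbo	S006	          1
rbo	S007	     0.9702
rbo	S008	 0.98549404
rbo	S009	     0.9702
rbo	S010	 0.99529404
rbo	S011	     0.9902
rbo	S012	          1
rbo	S013	0.9888913733
rbo	S014	     0.9902
rbo	S015	0.9935973333
rbo	S016	       0.98
rbo	S017	0.9637973333
rbo	S018	 0.98549404
rbo	S019	          1
rbo	S020	0.9790913733
rbo	KO_TF001	 0.98549404
rbo	KO_TF002	0.9790913733
rbo	KO_TF003	          1
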