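stage,move_type,n
all,short_independent,15916
all,long_independent,37675
all,short_accompanied,18458
all,long_accompanied,32834
child,short_independent,4951
child,long_independent,13488
child,short_accompanied,11607
child,long_accompanied,19958
adolescent,short_independent,8516
adolescent,long_independent,19154
adolescent,short_accompanied,4668
adolescent,long_accompanied,8678
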